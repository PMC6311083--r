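# The master/worker estimation driver and its reduction step.

pseudo <- pseudomonas_model()
pseudo_K <- as_parametrization(pseudo$network,
                               list(x = c(0, 2, 1, 2), y = c(0, 1)))

test_that("single-candidate evaluation follows the acceptance rule", {
  expect_true(evaluate_parametrization(pseudo$network, pseudo_K,
                                       pseudo$formulas))
  expect_true(evaluate_parametrization(pseudo$network, pseudo_K, list("TRUE")))
  expect_false(evaluate_parametrization(pseudo$network, pseudo_K, list("FALSE")))
})

test_that("estimation agrees with a single-loop brute-force sweep", {
  fit <- brn_estimate(pseudo$network, pseudo$formulas)
  expect_identical(fit$total_evaluated, 324)
  expect_gt(length(fit$accepted_indices), 0)
  expect_true(all(diff(fit$accepted_indices) > 0))  # strictly increasing

  brute <- brute_force_accepted(pseudo$network,
                                lapply(pseudo$formulas, parse_ctl,
                                       network = pseudo$network))
  K <- coef(fit)
  expect_identical(nrow(K), length(brute))
  brute_keys <- sort(vapply(brute, paste, "", collapse = ","))
  fit_keys <- sort(apply(K, 1L, paste, collapse = ","))
  expect_identical(unname(fit_keys), brute_keys)

  # the hand-checked homeostasis model is among the accepted set
  idx <- parametrization_to_index(parameter_slots(pseudo$network), pseudo_K)
  expect_true(idx %in% fit$accepted_indices)
})

test_that("results are invariant to the worker count", {
  fits <- lapply(c(1L, 2L, 4L, 8L), function(w) {
    brn_estimate(pseudo$network, pseudo$formulas, workers = w)
  })
  base_lines <- write_results(fits[[1]])
  for (f in fits[-1]) {
    expect_identical(f$accepted_indices, fits[[1]]$accepted_indices)
    expect_identical(write_results(f), base_lines)   # byte-identical output
    expect_identical(f$total_evaluated, 324)
  }
})

test_that("trivial formulas accept everything or nothing", {
  fx <- random_brn(2, 1, 0.5, seed = 5)
  sl <- parameter_slots(fx$network)
  all_fit <- brn_estimate(fx$network, "TRUE", workers = 2L)
  expect_identical(all_fit$accepted_indices,
                   seq_len(parametrization_count(sl)) - 1)
  none_fit <- brn_estimate(fx$network, "FALSE", workers = 2L)
  expect_length(none_fit$accepted_indices, 0)
  expect_identical(none_fit$total_evaluated, parametrization_count(sl))
})

test_that("PARA restrictions propagate into estimation", {
  fit <- brn_estimate(pseudo$network, pseudo$formulas,
                      para = list("K_x:{}" = 0))
  expect_identical(fit$total_evaluated, 108)
  full <- brn_estimate(pseudo$network, pseudo$formulas)
  # restricted space only contains models whose K_x:{} is 0
  expect_true(all(coef(fit)[, "K_x:{}"] == 0))
  expect_true(all(apply(coef(fit), 1, paste, collapse = ",") %in%
                    apply(coef(full), 1, paste, collapse = ",")))
})

test_that("diagnostics count first-failing formulas", {
  fit <- brn_estimate(pseudo$network, pseudo$formulas, diagnostics = TRUE)
  expect_identical(sum(fit$diagnostics) + length(fit$accepted_indices), 324)
  expect_length(fit$diagnostics, 2L)
})

test_that("the reduction step merges disjoint partials and rejects overlap", {
  sl <- parameter_slots(pseudo$network)
  blocks <- block_partition(324, 3)
  partials <- lapply(seq_len(3), function(b) {
    brnest:::.estimate_block(pseudo$network, sl,
                             lapply(pseudo$formulas, parse_ctl,
                                    network = pseudo$network),
                             blocks$start[b], blocks$end[b], 1e6, FALSE)
  })
  merged <- merge_results(partials[c(2, 3, 1)])  # order must not matter
  whole <- brn_estimate(pseudo$network, pseudo$formulas)
  expect_identical(merged$accepted_indices, whole$accepted_indices)
  expect_identical(merged$total_evaluated, 324)

  expect_error(merge_results(list()), "non-empty")
  expect_error(merge_results(partials[c(1, 1)]), "overlapping")
  two_empty <- merge_results(lapply(1:2, function(b) {
    brnest:::.estimate_block(pseudo$network, sl, list(parse_ctl("FALSE",
      pseudo$network)), 0, 0, 1e6, FALSE)
  }))
  expect_length(two_empty$accepted_indices, 0)
})

test_that("a failing worker names its index range", {
  # formulas referencing an entity absent from the graph fail inside the block
  alien <- parse_ctl("g9=1", random_brn(9, 1, 0, seed = 1)$network)
  expect_error(
    suppressWarnings(brn_estimate(pseudo$network, list(alien), workers = 2L)),
    "index range")
})
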