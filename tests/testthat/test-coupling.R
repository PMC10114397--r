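test_that("orientation negates cost indicators so larger is always better", {
  d <- tibble::tibble(subject_id = "S1", d_va = -0.9, d_brbp = -3,
                      d_hpep = -0.64, d_sa = 2)
  o <- orient_differences(d)
  expect_equal(unlist(o[c("d_va", "d_brbp", "d_hpep", "d_sa")]),
               c(d_va = 0.9, d_brbp = 3, d_hpep = 0.64, d_sa = 2))
  # zero vector is a fixed point; all-benefit map is the identity
  z <- tibble::tibble(d_va = 0, d_brbp = 0, d_hpep = 0, d_sa = 0)
  expect_equal(orient_differences(z), z)
  all_benefit <- setNames(rep("benefit", 4), names(default_orientation()))
  expect_equal(orient_differences(d, all_benefit), d)
  expect_error(orient_differences(d[-2]), class = "vc_completeness_error")
  d$d_sa <- NA_real_
  expect_error(orient_differences(d), class = "vc_completeness_error")
})

test_that("min-max coupling puts the best subject at 1 and the worst at 0", {
  diffs <- tibble::tibble(
    subject_id = c("best", "mid", "worst"),
    d_va = c(-1, -0.5, 0), d_brbp = c(-4, -1, 1),
    d_hpep = c(-0.8, -0.2, 0.3), d_sa = c(3, 1, -1)
  )
  w <- setNames(rep(0.25, 4), c("d_va", "d_brbp", "d_hpep", "d_sa"))
  sc <- coupling_index(diffs, w)
  expect_equal(sc$ci[sc$subject_id == "best"], 1)
  expect_equal(sc$ci[sc$subject_id == "worst"], 0)
  expect_true(all(sc$ci >= 0 & sc$ci <= 1))
  # index decomposes exactly into its per-indicator contributions
  expect_equal(sc$ci, rowSums(sc[paste0("w_u_", names(w))]), tolerance = 1e-12)
})

test_that("complementary subjects under equal weights tie at 0.5", {
  diffs <- tibble::tibble(
    subject_id = c("A", "B"),
    d_va = c(-1, 0), d_brbp = c(-1, 0), d_hpep = c(0, -1), d_sa = c(0, 1)
  )
  w <- setNames(rep(0.25, 4), c("d_va", "d_brbp", "d_hpep", "d_sa"))
  sc <- coupling_index(diffs, w)
  expect_equal(sc$ci, c(0.5, 0.5))
  expect_equal(sc$subject_id, c("A", "B"))  # lexicographic tie order
})

test_that("the index is monotone in every oriented component", {
  set.seed(50)
  w <- setNames(c(0.4, 0.3, 0.2, 0.1), c("d_va", "d_brbp", "d_hpep", "d_sa"))
  for (i in 1:10) {
    diffs <- tibble::tibble(
      subject_id = sprintf("P%02d", 1:6),
      d_va = rnorm(6), d_brbp = rnorm(6), d_hpep = rnorm(6), d_sa = rnorm(6)
    )
    base_ci <- rank_subjects(coupling_index(diffs, w))
    col <- sample(names(w), 1)
    improved <- diffs
    # improving one subject's indicator in the benefit direction
    sign <- if (default_orientation()[[col]] == "cost") -1 else 1
    improved[[col]][3] <- improved[[col]][3] + sign * 0.5
    new_ci <- coupling_index(improved, w)
    expect_gte(new_ci$ci[new_ci$subject_id == "P03"] -
                 base_ci$ci[base_ci$subject_id == "P03"], -1e-12)
  }
})

test_that("degenerate weight on one indicator reduces to that indicator's ranking", {
  set.seed(51)
  diffs <- tibble::tibble(
    subject_id = sprintf("P%02d", 1:8),
    d_va = rnorm(8), d_brbp = rnorm(8), d_hpep = rnorm(8), d_sa = rnorm(8)
  )
  w <- setNames(c(0, 0, 0, 1), c("d_va", "d_brbp", "d_hpep", "d_sa"))
  sc <- coupling_index(diffs, w)
  expect_equal(sc$subject_id,
               diffs$subject_id[order(-diffs$d_sa, diffs$subject_id)])
})

test_that("min-max coupling is invariant to positive rescaling of a column", {
  set.seed(52)
  diffs <- tibble::tibble(
    subject_id = sprintf("P%02d", 1:7),
    d_va = rnorm(7), d_brbp = rnorm(7), d_hpep = rnorm(7), d_sa = rnorm(7)
  )
  w <- setNames(c(0.3, 0.3, 0.2, 0.2), c("d_va", "d_brbp", "d_hpep", "d_sa"))
  sc <- coupling_index(diffs, w)
  scaled <- dplyr::mutate(diffs, d_hpep = 57.3 * d_hpep)  # degrees -> radians-ish
  expect_equal(coupling_index(scaled, w)$ci, sc$ci, tolerance = 1e-12)
})

test_that("constant indicator columns make min-max normalization fail loudly", {
  diffs <- tibble::tibble(
    subject_id = c("A", "B", "C"),
    d_va = c(-1, -0.5, 0), d_brbp = c(-2, -2, -2),
    d_hpep = c(-0.8, -0.2, 0.3), d_sa = c(3, 1, -1)
  )
  w <- setNames(rep(0.25, 4), c("d_va", "d_brbp", "d_hpep", "d_sa"))
  expect_error(coupling_index(diffs, w), class = "vc_degenerate_error")
  expect_error(coupling_index(diffs, w), "d_brbp")
})

test_that("zscore normalization gives an alternative cohort-relative index", {
  set.seed(53)
  diffs <- tibble::tibble(
    subject_id = sprintf("P%02d", 1:9),
    d_va = rnorm(9), d_brbp = rnorm(9), d_hpep = rnorm(9), d_sa = rnorm(9)
  )
  w <- setNames(rep(0.25, 4), c("d_va", "d_brbp", "d_hpep", "d_sa"))
  sc <- coupling_index(diffs, w, normalization = "zscore")
  expect_equal(mean(sc$ci), 0, tolerance = 1e-10)
  expect_equal(sc$ci, rowSums(sc[paste0("w_u_", names(w))]), tolerance = 1e-12)
})

test_that("validation-cohort ordering reproduces the narrated relations", {
  cohort <- validation_cohort(fill_missing = TRUE)
  diffs <- difference_scores(cohort)
  for (w in list(run_critic(diffs[c("subject_id", "d_va", "d_brbp",
                                    "d_hpep", "d_sa")])$weights,
                 reference_cohort()$weights)) {
    sc <- coupling_index(diffs, w)
    ci <- setNames(sc$ci, sc$subject_id)
    expect_equal(names(which.max(ci)), "S1")   # S1: largest improvement
    expect_lt(ci[["S5"]], ci[["S4"]])          # mild case scores below S4
  }
})

test_that("rank_subjects orders by descending index with stable id ties", {
  sc <- tibble::tibble(subject_id = c("B", "A", "C"), ci = c(0.3, 0.3, 0.6))
  ranked <- rank_subjects(sc)
  expect_equal(ranked$subject_id, c("C", "A", "B"))
  expect_equal(ranked$rank, 1:3)
  expect_error(rank_subjects(sc[0, ]), class = "vc_domain_error")
})
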