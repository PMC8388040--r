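test_that("E-values follow the exponential-tail law exactly", {
  params <- stat_params(1.0, log(0.1 * 1000 * 100), M_cal = 1000,
                        n_cal = 100)
  expect_equal(params$K, 0.1, tolerance = 1e-12)
  expect_equal(evalue(20, params, 1000, 100), 1e4 * exp(-20),
               tolerance = 1e-12)
  # score shift multiplies E by exp(-lambda * delta)
  expect_equal(evalue(23, params, 1000, 100),
               evalue(20, params, 1000, 100) * exp(-3), tolerance = 1e-12)
  # linear in M and in n
  expect_equal(evalue(20, params, 2000, 100),
               2 * evalue(20, params, 1000, 100), tolerance = 1e-12)
  expect_equal(evalue(20, params, 1000, 300),
               3 * evalue(20, params, 1000, 100), tolerance = 1e-12)
  expect_error(stat_params(-1, 0), "lambda")
})

test_that("p-values approximate E-values in the small-E regime", {
  expect_equal(pvalue_from_evalue(0), 0)
  expect_equal(pvalue_from_evalue(0.05), 1 - exp(-0.05), tolerance = 1e-12)
  expect_error(pvalue_from_evalue(-1), "non-negative")
  E <- 10^seq(-8, log10(0.05), length.out = 40)
  p <- pvalue_from_evalue(E)
  expect_true(all(abs(p - E) / E <= 0.025))
  expect_true(all(diff(pvalue_from_evalue(c(0.1, 1, 10, 100))) > 0))
})

test_that("the synthetic score function has an exact exponential tail", {
  fn <- exp_tail_score_fn(50, 1.0, seed = 3)
  set.seed(9)
  scores <- attr(fn, "batch")(matrix(sample.int(4, 50 * 2e5, TRUE),
                                     nrow = 50))
  for (s in c(2, 4, 6)) {
    p_hat <- mean(scores >= s)
    p <- exp(-s)
    expect_lt(abs(p_hat - p), 3 * sqrt(p * (1 - p) / 2e5))
  }
  # deterministic in the sequence, sensitive to single-character changes
  x <- strrep("ACGTA", 10)
  expect_equal(fn(x), fn(x))
  y <- x; substr(y, 25, 25) <- "T"
  expect_false(is.na(fn(y)))  # rehashes without error
  # batch and scalar scorers agree
  qs <- pangaln:::random_dna(20, 50)
  expect_equal(vapply(qs, fn, 1L, USE.NAMES = FALSE),
               attr(fn, "batch")(vapply(qs, pangaln:::dna_codes,
                                        integer(50))))
})

test_that("naive calibration recovers a known exponential tail", {
  fn <- exp_tail_score_fn(100, 1.0, seed = 1)
  set.seed(13)
  cal <- naive_calibrate(fn, 100, 2e5)
  # binomial noise of the ccdf at 2e5 samples bounds the achievable accuracy
  expect_equal(cal$params$lam, 1.0, tolerance = 0.08)
  expect_equal(cal$params$C, 0, tolerance = 0.5)
  expect_equal(cal$params$provenance, "naive")
  # degenerate: constant score function has no tail to fit
  const_fn <- function(x) 5L
  set.seed(14)
  expect_error(suppressWarnings(naive_calibrate(const_fn, 10, 100)),
               "tail window")
})

test_that("proposals preserve length, differ from the source, edit distance <= 2", {
  set.seed(17)
  x <- strrep("ACGT", 10)
  for (i in 1:300) {
    y <- mh_propose(x)
    expect_equal(nchar(y), nchar(x))
    expect_false(identical(y, x))
    d <- utils::adist(x, y)[1, 1]
    expect_lte(d, 2)
  }
  # substitution move on a homopolymer changes exactly one position
  set.seed(18)
  subs <- replicate(200, mh_propose("AAAAAAAA"))
  ham <- vapply(subs, function(y) {
    sum(strsplit(y, "")[[1]] != strsplit("AAAAAAAA", "")[[1]])
  }, 1L)
  expect_true(any(ham == 1))  # substitutions occur
  expect_error(mh_propose("A"), "length")
})

test_that("MH acceptance probability follows min(1, exp(lambda0 * ds))", {
  # score increase: always accepted
  up_fn <- function(y) 100L
  set.seed(19)
  st <- mh_step(strrep("ACGT", 5), 1L, up_fn, 1.0)
  expect_true(st$accepted)
  # score decrease by 1 at lambda0 = 1: accept rate exp(-1) (binomial 3 sigma)
  down_fn <- function(y) 0L
  set.seed(20)
  acc <- mean(replicate(4000, mh_step(strrep("ACGT", 5), 1L, down_fn,
                                      1.0)$accepted))
  p <- exp(-1)
  expect_lt(abs(acc - p), 3 * sqrt(p * (1 - p) / 4000))
  expect_error(mh_step("ACGT", 0L, down_fn, 0), "lambda0")
})

test_that("importance sampling is deterministic and near-flat under a good bias", {
  fn <- exp_tail_score_fn(60, 1.0, seed = 2)
  set.seed(21)
  s1 <- importance_sample(fn, 60, 0.95, 2000)
  set.seed(21)
  s2 <- importance_sample(fn, 60, 0.95, 2000)
  expect_identical(s1$samples, s2$samples)
  expect_identical(s1$counts, s2$counts)
  # near-flat histogram over a broad low-score interval
  cnt <- s1$counts[as.character(0:6)]
  expect_true(all(cnt >= 25))
  expect_lt(max(cnt) / min(cnt), 3)
  # empty request
  s0 <- importance_sample(fn, 60, 0.95, 0)
  expect_length(s0$samples, 0)
})

test_that("the generic R chain matches the compiled chain in distribution", {
  fn <- exp_tail_score_fn(30, 1.0, seed = 5)
  plain_fn <- function(x) fn(x)  # strips the exp_tail class: R path
  set.seed(22)
  a <- importance_sample(fn, 30, 0.9, 1500)
  set.seed(23)
  b <- importance_sample(plain_fn, 30, 0.9, 1500)
  # same score support and similar mass over the common low-score range
  pa <- a$counts[as.character(0:4)] / length(a$samples)
  pb <- b$counts[as.character(0:4)] / length(b$samples)
  expect_true(all(abs(pa - pb) < 0.08))
})

test_that("lambda estimation from reweighted tail masses is exact on affine data", {
  # R_s = round(1e6 * exp(-0.4 (s - 10))) with lambda0 = 0.5 makes
  # log T_s affine with slope -0.9; the support runs far enough beyond the
  # R_s >= 50 fit window (s <= 34) that truncation of the geometric tail
  # is negligible there
  s <- 10:60
  R <- round(1e6 * exp(-0.4 * (s - 10)))
  counts <- structure(list(counts = setNames(as.integer(R),
                                             as.character(s)),
                           lambda0 = 0.5), class = "mh_samples")
  expect_equal(estimate_lambda(counts), 0.9, tolerance = 0.02)
  # lambda0 = 0: T_s reduces to reverse cumulative counts
  counts0 <- structure(list(counts = setNames(c(100L, 100L, 100L, 100L),
                                              as.character(1:4)),
                            lambda0 = 0), class = "mh_samples")
  tm <- pangaln:::tail_masses(counts0$counts, 0)
  expect_equal(exp(tm$logT), c(400, 300, 200, 100))
  # scores below the count threshold do not move the estimate
  counts2 <- structure(list(counts = setNames(as.integer(c(R, 3, 2)),
                                              as.character(c(s, 70, 80))),
                            lambda0 = 0.5), class = "mh_samples")
  expect_equal(estimate_lambda(counts2), estimate_lambda(counts),
               tolerance = 1e-6)
  few <- structure(list(counts = setNames(c(60L, 60L), c("1", "2")),
                        lambda0 = 0.5), class = "mh_samples")
  expect_error(estimate_lambda(few), "fewer than 3")
})

test_that("C estimation is exact when the top-decile ccdf lies on the line", {
  # construct scores whose empirical ccdf is exactly exp(5 - s) on the
  # top-decile support
  N <- 10000L
  scores <- integer(0)
  for (s in 9:6) {
    n_ge <- round(N * exp(5 - s))
    scores <- c(scores, rep(s, n_ge - length(scores)))
  }
  scores <- c(scores, rep(0L, N - length(scores)))
  expect_equal(estimate_C(scores, 1.0), 5, tolerance = 0.01)
  expect_error(estimate_C(1:5, 1.0), "at least 10")
})
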