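# Exponential-tail score statistics: E-values/p-values and estimation of
# (lambda, C) by naive sampling and Metropolis-Hastings importance sampling.

#' Calibrated score-statistics parameters
#'
#' Holds the exponential-tail parameters of the best-hit score distribution:
#' `log p_s ~ C - lambda * s` at calibration reference size `M_cal` and
#' query length `n_cal`, with `K = exp(C) / (M_cal * n_cal)` so that
#' E-values rescale to other reference/query sizes.
#'
#' @param lam tail decay rate lambda (> 0)
#' @param C intercept of the affine tail `log p_s ~ C - lambda s`
#' @param regime `"ungapped"` or `"gapped"`
#' @param M_cal reference (graph) size used during calibration
#' @param n_cal query length used during calibration
#' @param provenance `"naive"` or `"importance"`
#' @param lambda0 importance-sampling bias rate, if any
#' @param num_samples number of samples used
#' @return an object of class `stat_params`
#' @export
stat_params <- function(lam, C, regime = c("ungapped", "gapped"),
                        M_cal = 1, n_cal = 1,
                        provenance = c("naive", "importance"),
                        lambda0 = NA_real_, num_samples = NA_integer_) {
  regime <- match.arg(regime)
  provenance <- match.arg(provenance)
  if (!is.finite(lam) || lam <= 0) stop("lambda must be positive")
  M_cal <- as.numeric(M_cal); n_cal <- as.numeric(n_cal)
  structure(list(lam = lam, C = C, K = exp(C) / (M_cal * n_cal),
                 regime = regime, M_cal = M_cal, n_cal = n_cal,
                 provenance = provenance, lambda0 = lambda0,
                 num_samples = num_samples),
            class = "stat_params")
}

#' @export
print.stat_params <- function(x, ...) {
  cat(sprintf(
    "stat_params (%s, %s): lambda = %.4f, C = %.4f, K = %.4g (M_cal = %g, n_cal = %g)\n",
    x$regime, x$provenance, x$lam, x$C, x$K, x$M_cal, x$n_cal))
  invisible(x)
}

#' @export
tidy.stat_params <- function(x, ...) {
  tibble(term = c("lambda", "C", "K"),
         estimate = c(x$lam, x$C, x$K))
}

#' @export
glance.stat_params <- function(x, ...) {
  tibble(regime = x$regime, provenance = x$provenance, lambda = x$lam,
         C = x$C, K = x$K, M_cal = x$M_cal, n_cal = x$n_cal,
         lambda0 = x$lambda0, num_samples = x$num_samples)
}

#' Broom-style generics
#' @param x object to tidy
#' @param ... unused
#' @name tidiers
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidiers
#' @export
glance <- function(x, ...) UseMethod("glance")

#' Expected number of chance hits at score >= s
#'
#' `E_s = K * M * n * exp(-lambda * s)` for a reference of size `M` and a
#' query of length `n`, with `(lambda, K)` taken from calibrated parameters.
#'
#' @param s integer score (vectorized)
#' @param params a [stat_params()] object
#' @param M reference size (total graph label length)
#' @param n query length
#' @return E-value(s)
#' @export
evalue <- function(s, params, M, n) {
  if (!inherits(params, "stat_params")) stop("params must be stat_params")
  if (any(c(M, n) < 1)) stop("M and n must be at least 1")
  params$K * M * n * exp(-params$lam * s)
}

#' p-value of at least one chance hit
#'
#' `p = 1 - exp(-E)` under the Poisson approximation; for small E the
#' p-value and E-value are practically identical.
#'
#' @param E E-value(s), non-negative
#' @return p-value(s)
#' @export
pvalue_from_evalue <- function(E) {
  if (any(E < 0)) stop("E-value must be non-negative")
  -expm1(-E)
}

#' Calibrate tail parameters by naive sampling
#'
#' Draws iid uniform random DNA queries of length `n`, scores each with
#' `score_fn` (the top alignment score of the query), and fits an affine
#' line to the logarithmic complementary cumulative score distribution over
#' the tail window of empirical probabilities between `p_lo` and `p_hi`.
#'
#' @param score_fn function mapping a DNA string to an integer top score
#' @param n query length
#' @param num_samples number of random queries (>= 1e4 recommended)
#' @param M_cal reference size recorded on the calibration (use the graph's
#'   `M` when `score_fn` searches a graph)
#' @param regime `"ungapped"` or `"gapped"`
#' @param p_lo,p_hi tail window of empirical ccdf values used in the fit
#' @return list with `params` (a [stat_params()]), `scores` (all sampled
#'   top scores) and `fit` (tibble of the fitted tail points); class
#'   `naive_calibration`
#' @export
naive_calibrate <- function(score_fn, n, num_samples, M_cal = 1,
                            regime = "ungapped",
                            p_lo = 1e-4, p_hi = 1e-2) {
  num_samples <- as.integer(num_samples)
  if (num_samples < 1e4) {
    warning("fewer than 10^4 naive samples; tail estimates will be noisy")
  }
  scores <- integer(num_samples)
  batch <- attr(score_fn, "batch")  # vectorized scorer over code columns
  chunk <- if (is.null(batch)) 2000L else 20000L
  done <- 0L
  while (done < num_samples) {
    nb <- min(chunk, num_samples - done)
    scores[(done + 1L):(done + nb)] <- if (is.null(batch)) {
      vapply(random_dna(nb, n), function(q) as.integer(score_fn(q)), 1L,
             USE.NAMES = FALSE)
    } else {
      batch(matrix(sample.int(4L, n * nb, replace = TRUE), nrow = n))
    }
    done <- done + nb
  }
  fit <- fit_ccdf_tail(scores, p_lo, p_hi)
  params <- stat_params(fit$lam, fit$C, regime = regime, M_cal = M_cal,
                        n_cal = n, provenance = "naive",
                        num_samples = num_samples)
  structure(list(params = params, scores = scores, fit = fit$points),
            class = "naive_calibration")
}

# least-squares fit of log ccdf over the tail window
fit_ccdf_tail <- function(scores, p_lo = 1e-4, p_hi = 1e-2) {
  N <- length(scores)
  s <- sort(unique(scores))
  pe <- vapply(s, function(v) sum(scores >= v), 1L) / N
  keep <- pe >= p_lo & pe <= p_hi
  if (sum(keep) < 3L) {
    stop("fewer than 3 ccdf points in the tail window [", p_lo, ", ", p_hi,
         "]; increase num_samples or widen the window")
  }
  pts <- tibble(score = s[keep], p = pe[keep], logp = log(pe[keep]))
  f <- lm(logp ~ score, data = pts)
  list(lam = -unname(coef(f)[2L]), C = unname(coef(f)[1L]), points = pts)
}

#' Propose a neighbor sequence for the Metropolis-Hastings chain
#'
#' One of three equiprobable length-preserving edits: substitution at a
#' uniform position (to a different base); insertion of a uniform base at a
#' uniform position with deletion of the left or right terminal base; or
#' deletion at a uniform position with insertion of a uniform base at the
#' left or right end. The proposal differs from `x` and has edit distance
#' at most 2 from it.
#'
#' @param x DNA string of length >= 2
#' @return proposed DNA string of the same length
#' @export
mh_propose <- function(x) {
  cx <- dna_codes(x)
  n <- length(cx)
  if (n < 2L) stop("sequence must have length at least 2")
  repeat {
    y <- cx
    mv <- sample.int(3L, 1L)
    if (mv == 1L) {
      i <- sample.int(n, 1L)
      y[i] <- ((cx[i] - 1L + sample.int(3L, 1L)) %% 4L) + 1L
    } else if (mv == 2L) {
      i <- sample.int(n, 1L)
      nb <- sample.int(4L, 1L)
      core <- if (sample.int(2L, 1L) == 1L) cx[-1L] else cx[-n]
      y <- append(core, nb, after = i - 1L)
    } else {
      i <- sample.int(n, 1L)
      nb <- sample.int(4L, 1L)
      core <- cx[-i]
      y <- if (sample.int(2L, 1L) == 1L) c(nb, core) else c(core, nb)
    }
    if (!identical(y, cx)) return(codes_to_dna(y))
  }
}

#' One Metropolis-Hastings step
#'
#' Proposes a neighbor of `x` and accepts it with probability
#' `min(1, exp(lambda0 * (s_y - s_x)))`: score increases are always
#' accepted, decreases only with exponentially small probability.
#'
#' @param x current DNA string
#' @param s_x its score
#' @param score_fn scoring black box
#' @param lambda0 positive bias rate
#' @return list with `x`, `s_x` (possibly updated) and `accepted`
#' @export
mh_step <- function(x, s_x, score_fn, lambda0) {
  if (lambda0 <= 0) stop("lambda0 must be positive")
  y <- mh_propose(x)
  s_y <- score_fn(y)
  accepted <- s_y >= s_x || runif(1L) < exp(lambda0 * (s_y - s_x))
  if (accepted) list(x = y, s_x = s_y, accepted = TRUE)
  else list(x = x, s_x = s_x, accepted = FALSE)
}

#' Importance sampling of the score tail
#'
#' Runs the Metropolis-Hastings chain from a uniform random start,
#' discarding the first `burn_in` recorded samples. With `lambda0` slightly
#' below the true tail rate, the sampled scores cover a broad range of the
#' rare-event tail.
#'
#' Samples must be spaced far enough apart that the sequence changes
#' considerably between them; about `2n/3` accepted moves suffice. With
#' `sampling = "proposals"` (the default) the current state is recorded at
#' fixed proposal intervals of `accepts_per_sample` divided by a nominal
#' acceptance rate of one half, i.e. every `ceiling(4n/3)` proposals by
#' default. This time-uniform scheme weights every state by how long the
#' chain holds it, which is what the reweighted tail estimator assumes;
#' recording at every `accepts_per_sample`-th acceptance
#' (`sampling = "accepts"`) samples the jump chain instead, which
#' under-represents high scores whenever holding times grow with the score
#' (see the methods vignette).
#'
#' For the synthetic exponential-tail score functions created by
#' [exp_tail_score_fn()] a compiled chain is used; any other score function
#' is driven through [mh_step()].
#'
#' @param score_fn scoring black box (DNA string -> integer score)
#' @param n sequence length
#' @param lambda0 bias rate, typically 0.95 times a naive estimate of lambda
#' @param num_samples number of score samples to record (after burn-in)
#' @param accepts_per_sample nominal acceptances between recorded samples
#'   (default `ceiling(2 n / 3)`)
#' @param burn_in initial samples to discard (default 5)
#' @param sampling `"proposals"` (time-uniform, default) or `"accepts"`
#'   (jump chain)
#' @return object of class `mh_samples`: list with `counts` (named integer
#'   vector R_s of sample counts per score), `samples`, `lambda0`, `n`,
#'   `accepts_per_sample`, `burn_in`, `acceptance_rate`
#' @export
importance_sample <- function(score_fn, n, lambda0, num_samples,
                              accepts_per_sample = ceiling(2 * n / 3),
                              burn_in = 5L,
                              sampling = c("proposals", "accepts")) {
  sampling <- match.arg(sampling)
  interval <- if (sampling == "proposals") {
    as.integer(ceiling(accepts_per_sample / 0.5))
  } else 0L
  num_samples <- as.integer(num_samples)
  if (num_samples <= 0L) {
    return(structure(list(counts = integer(0), samples = integer(0),
                          lambda0 = lambda0, n = n,
                          accepts_per_sample = accepts_per_sample,
                          burn_in = burn_in, acceptance_rate = NA_real_),
                     class = "mh_samples"))
  }
  if (inherits(score_fn, "exp_tail_score_fn")) {
    at <- attributes(score_fn)
    res <- mh_chain_exp_cpp(n, at$lam_true, at$off, at$base, at$p,
                            lambda0, num_samples + burn_in,
                            as.integer(accepts_per_sample),
                            as.integer(burn_in), interval)
    samples <- res$samples
    rate <- res$accepts / res$proposals
  } else {
    x <- random_dna(1L, n)
    s_x <- score_fn(x)
    samples <- integer(num_samples)
    kept <- 0L; drawn <- 0L; acc_since <- 0L
    proposals <- 0; accepts <- 0
    record <- function() {
      drawn <<- drawn + 1L
      if (drawn > burn_in) {
        kept <<- kept + 1L
        samples[kept] <<- s_x
      }
    }
    while (kept < num_samples) {
      st <- mh_step(x, s_x, score_fn, lambda0)
      proposals <- proposals + 1
      if (st$accepted) {
        x <- st$x; s_x <- st$s_x
        accepts <- accepts + 1
        if (interval == 0L) {
          acc_since <- acc_since + 1L
          if (acc_since >= accepts_per_sample) {
            acc_since <- 0L
            record()
          }
        }
      }
      if (interval > 0L && proposals %% interval == 0) record()
    }
    rate <- accepts / proposals
  }
  tb <- table(samples)
  counts <- as.integer(tb)
  names(counts) <- names(tb)
  structure(list(counts = counts, samples = as.integer(samples),
                 lambda0 = lambda0, n = n,
                 accepts_per_sample = as.integer(accepts_per_sample),
                 burn_in = as.integer(burn_in),
                 acceptance_rate = rate),
            class = "mh_samples")
}

#' @export
print.mh_samples <- function(x, ...) {
  cat(sprintf(
    "mh_samples: %d samples over scores [%s, %s], lambda0 = %.4f, acceptance rate %.3f\n",
    length(x$samples),
    if (length(x$samples)) min(x$samples) else NA,
    if (length(x$samples)) max(x$samples) else NA,
    x$lambda0, x$acceptance_rate))
  invisible(x)
}

# reweighted reverse-cumulative tail masses T_s = sum_{s' >= s} R_s' e^{-lambda0 s'}
# computed on a log scale to avoid underflow at large scores
tail_masses <- function(counts, lambda0) {
  s <- as.integer(names(counts))
  ord <- order(s)
  s <- s[ord]; R <- as.numeric(counts[ord])
  sh <- min(s)  # factor out exp(-lambda0 * min score)
  wt <- R * exp(-lambda0 * (s - sh))
  Ts <- rev(cumsum(rev(wt)))
  tibble(score = s, R = R, logT = log(Ts) - lambda0 * sh)
}

#' Estimate lambda from importance-sampling counts
#'
#' Computes the reweighted tail masses
#' `T_s = sum_{s' >= s} R_{s'} exp(-lambda0 s')` and fits a least-squares
#' line to `(s, log T_s)` over the scores where the raw counts are
#' consistently high (`R_s >= min_count`); returns the negated slope.
#'
#' @param counts an `mh_samples` object
#' @param min_count minimum count R_s for a score to enter the fit
#' @return estimated lambda
#' @export
estimate_lambda <- function(counts, min_count = 50L) {
  if (!inherits(counts, "mh_samples")) stop("counts must be mh_samples")
  tm <- tail_masses(counts$counts, counts$lambda0)
  pts <- tm[tm$R >= min_count, ]
  if (nrow(pts) < 3L) {
    stop("fewer than 3 scores with R_s >= ", min_count,
         "; draw more importance samples")
  }
  f <- lm(logT ~ score, data = pts)
  -unname(coef(f)[2L])
}

#' Estimate the intercept C from the naive top scores
#'
#' Uses the 10% highest scores of the naive sampling step (by count): over
#' the distinct scores s in that top decile with empirical ccdf `p_s`,
#' returns the mean of `log p_s + lam * s`.
#'
#' @param naive_scores integer scores from naive sampling (>= 10 values)
#' @param lam the (importance-sampling) estimate of lambda
#' @return estimated C
#' @export
estimate_C <- function(naive_scores, lam) {
  N <- length(naive_scores)
  if (N < 10L) stop("need at least 10 naive scores")
  n_top <- ceiling(N / 10)
  top <- sort(naive_scores, decreasing = TRUE)[seq_len(n_top)]
  support <- sort(unique(top))
  p_hat <- vapply(support, function(v) sum(naive_scores >= v), 1L) / N
  mean(log(p_hat) + lam * support)
}

#' Full two-stage calibration: naive sampling then importance sampling
#'
#' Runs [naive_calibrate()], sets the bias rate `lambda0` to
#' `lambda0_factor` times the naive lambda estimate, draws importance
#' samples, re-estimates lambda from the reweighted tail
#' ([estimate_lambda()]) and C from the naive top decile ([estimate_C()]).
#'
#' @inheritParams naive_calibrate
#' @param naive_samples number of naive samples
#' @param is_samples number of importance samples
#' @param lambda0_factor fraction of the naive lambda used as bias rate
#'   (slightly below 1 so the chain slightly underestimates the true rate)
#' @param min_count fit window rule for [estimate_lambda()]
#' @return list of class `is_calibration` with `params` (a [stat_params()]
#'   with provenance `"importance"`), `naive` (the naive calibration),
#'   `samples` (the `mh_samples`), `lambda0`
#' @export
calibrate_importance <- function(score_fn, n, naive_samples, is_samples,
                                 M_cal = 1, regime = "ungapped",
                                 lambda0_factor = 0.95, min_count = 50L) {
  nv <- naive_calibrate(score_fn, n, naive_samples, M_cal = M_cal,
                        regime = regime)
  lambda0 <- lambda0_factor * nv$params$lam
  smp <- importance_sample(score_fn, n, lambda0, is_samples)
  lam <- estimate_lambda(smp, min_count = min_count)
  C <- estimate_C(nv$scores, lam)
  params <- stat_params(lam, C, regime = regime, M_cal = M_cal, n_cal = n,
                        provenance = "importance", lambda0 = lambda0,
                        num_samples = as.integer(is_samples))
  structure(list(params = params, naive = nv, samples = smp,
                 lambda0 = lambda0),
            class = "is_calibration")
}

#' Absolute tail probabilities from importance sampling
#'
#' Rescales the reweighted tail masses `T_s` to absolute ccdf estimates by
#' anchoring them to the naive empirical ccdf over the score range where
#' both are well supported (naive count of at least `min_overlap`
#' observations at score >= s and `R_s >= min_overlap`).
#'
#' @param cal an `is_calibration` object
#' @param min_overlap support threshold for the anchoring region
#' @return tibble with `score`, `p_is` (anchored importance-sampling ccdf),
#'   `p_naive` (naive ccdf, NA beyond its support)
#' @export
is_tail_ccdf <- function(cal, min_overlap = 50L) {
  tm <- tail_masses(cal$samples$counts, cal$samples$lambda0)
  scores <- cal$naive$scores
  N <- length(scores)
  naive_ge <- vapply(tm$score, function(v) sum(scores >= v), 1L)
  p_naive <- ifelse(naive_ge > 0L, naive_ge / N, NA_real_)
  anchor <- naive_ge >= min_overlap & tm$R >= min_overlap
  if (!any(anchor)) stop("no overlap region between naive and importance sampling")
  logA <- mean(log(p_naive[anchor]) - tm$logT[anchor])
  tibble(score = tm$score, R = tm$R,
         p_is = exp(tm$logT + logA),
         p_naive = p_naive,
         anchored = anchor)
}
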