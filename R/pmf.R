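# Histogram free-energy profiles: the paper-style PMF machinery.
#
# Bin edges are anchored at integer multiples of the bin width, so with the
# 2-degree default an opening angle of -1 or +45 degrees falls exactly on a
# bin centre.  The reference state is the modal bin; free energies are
# dG_i = -kB T log(p_i / p_ref).  Empty bins stay missing (NA), never
# +/-Inf.

#' Histogram specification for free-energy profiles
#'
#' @param bin_width Bin width: 2 (degrees) for angular observables, 0.2
#'   (Angstrom) for translational ones.
#' @param range Optional `c(lo, hi)`; by default derived from the data and
#'   expanded to whole bins.
#' @param temperature Temperature in Kelvin (default 300).
#' @return An object of class `histogram_spec`.
#' @export
histogram_spec <- function(bin_width = 2, range = NULL, temperature = 300) {
  if (bin_width <= 0) stop("bin_width must be > 0")
  structure(list(bin_width = bin_width, range = range,
                 temperature = temperature), class = "histogram_spec")
}

#' @noRd
#' Bin edges anchored at multiples of the width
spec_edges <- function(spec, values) {
  rng <- spec$range
  if (is.null(rng)) rng <- range(values)
  w <- spec$bin_width
  lo <- floor(rng[1] / w) * w
  hi <- ceiling(rng[2] / w) * w
  if (hi <= lo) hi <- lo + w
  seq(lo, hi, by = w)
}

#' @noRd
new_pmf_profile <- function(df, spec, reference_index, n_runs = 1L) {
  structure(df, class = c("pmf_profile", "data.frame"),
            bin_width = spec$bin_width, temperature = spec$temperature,
            reference_index = reference_index, n_runs = n_runs)
}

#' Single-run potential of mean force from an observable series
#'
#' Bins the series, takes the bin with the highest count as the reference
#' state and reports `dG_i = -kB T log(n_i / n_ref)` per bin.  Modal-bin
#' ties are broken toward the lowest bin index (reported via a message);
#' empty interior bins are reported as `NA`.
#'
#' @param values Numeric vector (at least one finite value).
#' @param spec A [histogram_spec()].
#' @return A `pmf_profile` data frame with columns `center`, `count`,
#'   `dG`; the reference bin index is attached as attribute
#'   `"reference_index"`.
#' @export
#' @examples
#' pmf_from_series(rnorm(1e4), histogram_spec(bin_width = 0.2))
pmf_from_series <- function(values, spec = histogram_spec()) {
  values <- values[is.finite(values)]
  if (!length(values)) stop("need at least one finite value")
  edges <- spec_edges(spec, values)
  if (length(edges) == 2) {
    warning("all values fall in a single bin at this bin width")
  }
  counts <- tabulate(findInterval(values, edges, rightmost.closed = TRUE),
                     nbins = length(edges) - 1)
  centers <- edges[-length(edges)] + spec$bin_width / 2
  ref <- which(counts == max(counts))
  if (length(ref) > 1) {
    message("modal-bin tie; using lowest bin index ", ref[1])
    ref <- ref[1]
  }
  kT <- KB_KCAL * spec$temperature
  dG <- ifelse(counts > 0, -kT * log(counts / counts[ref]), NA_real_)
  new_pmf_profile(data.frame(center = centers, count = counts, dG = dG),
                  spec, ref)
}

#' Average free-energy profiles over runs
#'
#' Per-bin mean, standard error and 99 percent confidence interval
#' (Student-t, `mean +/- t[0.005, n-1] * SE`) across single-run profiles,
#' mirroring the evaluate-each-run-then-average rule.  Bins missing in any
#' run are reported missing.  With a single run only the mean is
#' returned.
#'
#' @param profiles List of `pmf_profile` objects on the same binning.
#' @param conf Confidence level for the interval (default 0.99).
#' @return A `pmf_profile` with columns `center`, `dG`, `se`, `ci_lo`,
#'   `ci_hi`, `n_runs`.
#' @export
average_profiles <- function(profiles, conf = 0.99) {
  if (!length(profiles)) stop("need at least one profile")
  w <- attr(profiles[[1]], "bin_width")
  centers <- sort(unique(unlist(lapply(profiles, function(p) p$center))))
  common <- Reduce(intersect, lapply(profiles, function(p) p$center))
  if (!length(common)) stop("profiles share no bins")
  vals <- vapply(profiles, function(p) {
    p$dG[match(centers, p$center)]
  }, numeric(length(centers)))
  vals <- matrix(vals, nrow = length(centers))
  n <- ncol(vals)
  ok_n <- rowSums(!is.na(vals))
  mean_g <- ifelse(ok_n == n, rowMeans(vals), NA_real_)
  if (n >= 2) {
    se <- ifelse(ok_n == n, apply(vals, 1, stats::sd) / sqrt(n), NA_real_)
    tq <- stats::qt(1 - (1 - conf) / 2, df = n - 1)
    ci_lo <- mean_g - tq * se
    ci_hi <- mean_g + tq * se
  } else {
    se <- ci_lo <- ci_hi <- rep(NA_real_, length(centers))
  }
  keep <- ok_n == n
  spec <- histogram_spec(bin_width = w,
                         temperature = attr(profiles[[1]], "temperature"))
  df <- data.frame(center = centers, dG = mean_g, se = se,
                   ci_lo = ci_lo, ci_hi = ci_hi, n_runs = n)[keep, ]
  rownames(df) <- NULL
  new_pmf_profile(df, spec, reference_index = NA_integer_, n_runs = n)
}

#' Free-energy difference between two coordinate values across runs
#'
#' Evaluates `dG(x1) - dG(x2)` per run (reference-independent) at the bins
#' containing `x1` and `x2`, then returns the across-run mean, standard
#' error and Student-t confidence interval.
#'
#' @param profiles List of single-run `pmf_profile` objects.
#' @param x1,x2 Coordinate values; each is mapped to its bin centre.
#' @param conf Confidence level (default 0.99).
#' @return Named numeric vector `c(estimate, se, ci_lo, ci_hi)`.
#' @export
profile_difference <- function(profiles, x1, x2, conf = 0.99) {
  at_bin <- function(p, x) {
    w <- attr(p, "bin_width")
    k <- which.min(abs(p$center - (floor(x / w) * w + w / 2)))
    p$dG[k]
  }
  d <- vapply(profiles, function(p) at_bin(p, x1) - at_bin(p, x2), numeric(1))
  if (anyNA(d)) stop("bin missing in at least one run")
  n <- length(d)
  est <- mean(d)
  if (n >= 2) {
    se <- stats::sd(d) / sqrt(n)
    tq <- stats::qt(1 - (1 - conf) / 2, df = n - 1)
    c(estimate = est, se = se, ci_lo = est - tq * se, ci_hi = est + tq * se)
  } else {
    c(estimate = est, se = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_)
  }
}

#' Convergence diagnostics from growing data windows
#'
#' Recomputes the averaged profile from the leading fraction of every
#' run's series (e.g. 2/3, 5/6 and the full data, mirroring
#' 40/50/60-nanosecond windows) and scores convergence as the maximal
#' absolute free-energy change between successive windows over their
#' common bins.
#'
#' @param series_per_run List of numeric vectors, one per run.
#' @param fractions Window fractions in (0, 1], increasing.
#' @param spec A [histogram_spec()].
#' @return List with `profiles` (one averaged `pmf_profile` per window)
#'   and `scores` (max |dG difference| between successive windows).
#' @export
convergence_windows <- function(series_per_run,
                                fractions = c(2 / 3, 5 / 6, 1),
                                spec = histogram_spec()) {
  if (any(fractions <= 0 | fractions > 1)) stop("fractions must be in (0, 1]")
  fractions <- sort(fractions)
  profiles <- lapply(fractions, function(fr) {
    runs <- lapply(series_per_run, function(v) {
      k <- max(1, floor(length(v) * fr))
      v[seq_len(k)]
    })
    if (any(vapply(runs, length, integer(1)) < 2)) {
      stop("window shorter than two samples")
    }
    average_profiles(lapply(runs, pmf_from_series, spec = spec))
  })
  scores <- vapply(seq_along(profiles)[-1], function(i) {
    a <- profiles[[i - 1]]; b <- profiles[[i]]
    common <- intersect(a$center, b$center)
    if (!length(common)) return(NA_real_)
    max(abs(a$dG[match(common, a$center)] - b$dG[match(common, b$center)]),
        na.rm = TRUE)
  }, numeric(1))
  list(profiles = profiles, fractions = fractions, scores = scores)
}

#' @export
print.pmf_profile <- function(x, ...) {
  cat("<pmf_profile>", nrow(x), "bins, bin width", attr(x, "bin_width"),
      "| T =", attr(x, "temperature"), "K | runs:", attr(x, "n_runs"), "\n")
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

#' Write a free-energy profile as TSV
#'
#' @param profile A `pmf_profile`.
#' @param path Output file.
#' @export
write_profile_tsv <- function(profile, path) {
  utils::write.table(as.data.frame(profile), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
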