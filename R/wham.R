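## shared binning: equal-width bins; a sample exactly at the upper edge
## falls in the last bin
.make_bins <- function(lo, hi, n_bins) {
  edges <- seq(lo, hi, length.out = n_bins + 1L)
  list(edges = edges, centers = (edges[-1] + edges[-(n_bins + 1L)]) / 2,
       width = (hi - lo) / n_bins)
}

.bin_index <- function(x, bins) {
  n <- length(bins$centers)
  idx <- floor((x - bins$edges[1]) / bins$width) + 1L
  idx[x == bins$edges[n + 1L]] <- n   # closed upper edge
  idx[idx < 1L | idx > n] <- NA_integer_
  idx
}

.new_pmf_profile <- function(bins, values, counts, temperature,
                             iterations = NA_integer_,
                             residual = NA_real_,
                             residual_history = numeric(0)) {
  structure(list(bin_edges = bins$edges, centers = bins$centers,
                 values = values, defined = counts > 0, counts = counts,
                 temperature = temperature, reference = NULL,
                 iterations = iterations, residual = residual,
                 residual_history = residual_history),
            class = "pmf_profile")
}

#' @export
print.pmf_profile <- function(x, ...) {
  cat(sprintf("PMF profile: %d bins over [%.3f, %.3f] nm, T = %g K\n",
              length(x$centers), min(x$bin_edges), max(x$bin_edges),
              x$temperature))
  cat(sprintf("  %d defined bins; reference: %s\n", sum(x$defined),
              if (is.null(x$reference)) "none"
              else sprintf("%.3f nm", x$reference)))
  if (!is.na(x$iterations))
    cat(sprintf("  WHAM: %d iterations, final residual %.3g kJ/mol\n",
                x$iterations, x$residual))
  invisible(x)
}

#' Reconstruct a PMF from umbrella windows by WHAM
#'
#' Solves the standard weighted-histogram self-consistency equations for
#' the unbiased bin probabilities
#' \deqn{P_j = \frac{\sum_i n_{ij}}{\sum_i N_i \exp[(f_i - c_{ij})/k_BT]},
#' \qquad f_i = -k_BT \ln \sum_j P_j e^{-c_{ij}/k_BT},}
#' with the bias \eqn{c_{ij} = \tfrac12 k_i (x_j - r_i)^2} evaluated at bin
#' centres, iterating until the largest change in any window free energy
#' \eqn{f_i} drops below `tol`. All accumulation is in log space
#' (log-sum-exp) for numerical stability. The PMF is
#' \eqn{-k_BT \ln P_j} on bins with at least one sample; empty bins are
#' flagged undefined. Use [set_reference()] to anchor the profile.
#'
#' @param windows list of `umbrella_window` objects (each with `center`,
#'   `spring`, `samples`).
#' @param n_bins number of equal-width bins (default 41).
#' @param temperature temperature, K.
#' @param tol convergence tolerance on `max |delta f_i|`, kJ/mol (> 0).
#' @param max_iter maximum number of iterations.
#' @param bin_range optional `c(lo, hi)` binning range; defaults to the
#'   span of all samples.
#' @return A `pmf_profile` with convergence diagnostics (`iterations`,
#'   `residual`, `residual_history` of the final iterations).
#' @references Kumar et al. (1992) J. Comput. Chem. 13, 1011-1021.
#' @export
wham <- function(windows, n_bins = 41L, temperature = 300, tol = 1e-6,
                 max_iter = 100000L, bin_range = NULL) {
  if (!is.list(windows) || length(windows) < 1L)
    stop("need at least one umbrella window", call. = FALSE)
  n_bins <- .check_count(n_bins, "n_bins")
  .check_scalar(tol, "tol", positive = TRUE)
  max_iter <- .check_count(max_iter, "max_iter")
  kT <- .kT(temperature)

  all_samples <- unlist(lapply(windows, `[[`, "samples"))
  if (!length(all_samples) || any(!is.finite(all_samples)))
    stop("windows must carry finite samples", call. = FALSE)
  if (is.null(bin_range)) bin_range <- range(all_samples)
  bins <- .make_bins(bin_range[1], bin_range[2], n_bins)

  n_win <- length(windows)
  counts <- matrix(0, nrow = n_bins, ncol = n_win)   # n_ij
  for (i in seq_len(n_win)) {
    idx <- .bin_index(windows[[i]]$samples, bins)
    idx <- idx[!is.na(idx)]
    if (!length(idx)) {
      lab <- windows[[i]]$label
      stop(sprintf(paste0("window %s (center %.3f nm) has no samples in ",
                          "the binning range: broken window overlap"),
                   if (is.null(lab)) as.character(i) else lab,
                   windows[[i]]$center), call. = FALSE)
    }
    counts[, i] <- tabulate(idx, nbins = n_bins)
  }
  n_tot <- rowSums(counts)                            # per-bin totals
  N_i <- colSums(counts)                              # frames in range
  defined <- n_tot > 0

  ## bias matrix c_ij / kT at bin centres
  cmat <- vapply(seq_len(n_win), function(i)
    0.5 * windows[[i]]$spring * (bins$centers - windows[[i]]$center)^2 / kT,
    numeric(n_bins))

  log_num <- ifelse(defined, log(n_tot), -Inf)
  log_N <- log(N_i)
  f <- numeric(n_win)                                 # f_i / kT, start at 0
  resid_hist <- numeric(0)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    ## log denominator per bin: logsumexp_i [log N_i + f_i - c_ij]
    a <- sweep(-cmat, 2, log_N + f, `+`)
    m <- apply(a, 1, max)
    log_den <- m + log(rowSums(exp(a - m)))
    log_p <- log_num - log_den
    ## new f_i = -logsumexp_j [log P_j - c_ij] (defined bins only)
    b <- log_p[defined] - cmat[defined, , drop = FALSE]
    mb <- apply(b, 2, max)
    f_new <- -(mb + log(colSums(exp(sweep(b, 2, mb, `-`)))))
    f_new <- f_new - f_new[1]                         # fix the gauge
    resid <- max(abs(f_new - f)) * kT
    resid_hist <- c(resid_hist, resid)
    f <- f_new
    if (resid < tol) break
    if (iter >= max_iter)
      stop(sprintf(paste0("WHAM did not converge in %d iterations ",
                          "(residual %.3g kJ/mol > tol %.3g)"),
                   max_iter, resid, tol), call. = FALSE)
  }

  values <- rep(NA_real_, n_bins)
  values[defined] <- -kT * log_p[defined]
  prof <- .new_pmf_profile(bins, values, n_tot, temperature,
                           iterations = iter, residual = resid,
                           residual_history = tail(resid_hist, 20L))
  prof
}

#' Anchor a PMF profile at a reference coordinate
#'
#' Subtracts the value of the bin containing `r_ref` from all defined bins,
#' so the profile is exactly zero there (the bulk reference convention).
#' Idempotent for a fixed `r_ref`.
#'
#' @param pmf a `pmf_profile`.
#' @param r_ref reference coordinate, nm; must fall in a defined bin.
#' @return The referenced `pmf_profile`.
#' @export
set_reference <- function(pmf, r_ref) {
  stopifnot(inherits(pmf, "pmf_profile"))
  .check_scalar(r_ref, "r_ref")
  bins <- list(edges = pmf$bin_edges, centers = pmf$centers,
               width = diff(pmf$bin_edges[1:2]))
  idx <- .bin_index(r_ref, bins)
  if (is.na(idx))
    stop(sprintf("reference %.3f nm lies outside the binned range [%.3f, %.3f]",
                 r_ref, min(pmf$bin_edges), max(pmf$bin_edges)),
         call. = FALSE)
  if (!pmf$defined[idx])
    stop(sprintf("reference %.3f nm falls in an undefined (empty) bin",
                 r_ref), call. = FALSE)
  pmf$values <- pmf$values - pmf$values[idx]
  pmf$reference <- r_ref
  pmf
}

#' Boltzmann inversion of an unbiased sample
#'
#' Direct histogram inversion `-kT log(count_j / N)` on non-empty bins; the
#' independent oracle against which [wham()] is checked on unbiased data.
#'
#' @param samples coordinate samples, nm.
#' @param n_bins number of bins.
#' @param temperature temperature, K.
#' @param bin_range optional binning range, `c(lo, hi)`.
#' @return A `pmf_profile`.
#' @export
boltzmann_invert <- function(samples, n_bins = 41L, temperature = 300,
                             bin_range = NULL) {
  if (!is.numeric(samples) || length(samples) < 1L ||
      any(!is.finite(samples)))
    stop("'samples' must be finite numeric of length >= 1", call. = FALSE)
  n_bins <- .check_count(n_bins, "n_bins")
  kT <- .kT(temperature)
  if (is.null(bin_range)) bin_range <- range(samples)
  bins <- .make_bins(bin_range[1], bin_range[2], n_bins)
  idx <- .bin_index(samples, bins)
  counts <- tabulate(idx[!is.na(idx)], nbins = n_bins)
  values <- rep(NA_real_, n_bins)
  values[counts > 0] <- -kT * log(counts[counts > 0] / sum(counts))
  .new_pmf_profile(bins, values, counts, temperature)
}

#' Write a PMF profile as CSV
#'
#' Columns `center_nm`, `dG_kJmol`, `count`, `defined`; undefined bins keep
#' their row with an empty `dG_kJmol` field and `defined = FALSE`.
#'
#' @param pmf a referenced `pmf_profile`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pmf <- function(pmf, path) {
  stopifnot(inherits(pmf, "pmf_profile"))
  if (is.null(pmf$reference))
    stop("profile must be referenced (set_reference) before writing",
         call. = FALSE)
  dg <- ifelse(pmf$defined, sprintf("%.12g", pmf$values), "")
  lines <- c("center_nm,dG_kJmol,count,defined",
             sprintf("%.12g,%s,%d,%s", pmf$centers, dg, pmf$counts,
                     ifelse(pmf$defined, "true", "false")))
  writeLines(lines, path)
  invisible(path)
}

#' Read a PMF profile written by [write_pmf()]
#'
#' @param path file path.
#' @param temperature temperature to attach, K.
#' @return A `pmf_profile` (bin edges reconstructed from the centres).
#' @export
read_pmf <- function(path, temperature = 300) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  centers <- df$center_nm
  w <- if (length(centers) > 1L) centers[2] - centers[1] else 1
  bins <- list(edges = c(centers - w / 2, centers[length(centers)] + w / 2),
               centers = centers, width = w)
  values <- suppressWarnings(as.numeric(df$dG_kJmol))
  prof <- .new_pmf_profile(bins, values, df$count, temperature)
  prof$defined <- df$defined == "true" | df$defined == "TRUE"
  prof
}
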