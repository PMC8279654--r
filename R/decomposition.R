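## internal: per-window component means, their standard errors and the
## reference-window index. dH is always assembled as the exact sum of the
## component differences, which guarantees the bookkeeping identity
## dH = dE_ww + dE_aaw + dE_aaaa on every row.
.window_energy_stats <- function(windows, ref_center) {
  if (!is.list(windows) || length(windows) < 1L)
    stop("need at least one window", call. = FALSE)
  for (w in windows)
    if (is.null(w$energies))
      stop(sprintf("window %s carries no per-frame energies", w$label),
           call. = FALSE)
  centers <- vapply(windows, `[[`, numeric(1), "center")
  spacing <- if (length(centers) > 1L) min(diff(sort(centers))) else Inf
  ref_idx <- which.min(abs(centers - ref_center))
  if (abs(centers[ref_idx] - ref_center) > spacing / 2 + 1e-9)
    stop(sprintf("no window within half a window spacing of ref_center = %g nm",
                 ref_center), call. = FALSE)
  stats_one <- function(w) {
    e <- w$energies
    n <- nrow(e)
    c(m_ww = mean(e$e_ww), m_aaw = mean(e$e_aaw), m_aaaa = mean(e$e_aaaa),
      se_ww = sd(e$e_ww) / sqrt(n), se_aaw = sd(e$e_aaw) / sqrt(n),
      se_aaaa = sd(e$e_aaaa) / sqrt(n), se_tot = sd(e$e_total) / sqrt(n))
  }
  s <- t(vapply(windows, stats_one, numeric(7)))
  list(centers = centers, stats = s, ref_idx = ref_idx)
}

#' Enthalpy profile from umbrella-window energies
#'
#' The enthalpy change at each window is the difference in time-averaged
#' potential energy between that window and the bulk reference window (the
#' window whose bias centre lies nearest `ref_center`). Standard errors
#' treat frames as independent and combine the two windows' errors in
#' quadrature; the reference row is exactly zero with zero error.
#'
#' @param windows list of `umbrella_window` objects carrying energies.
#' @param ref_center reference (bulk) coordinate, nm.
#' @return Data frame with columns `r`, `dH`, `se_dH`, ordered by `r`.
#' @export
enthalpy_profile <- function(windows, ref_center) {
  comp <- enthalpy_components_profile(windows, ref_center)
  data.frame(r = comp$r, dH = comp$dH, se_dH = comp$se_dH)
}

#' Component-wise enthalpy profile
#'
#' Splits the per-window enthalpy difference into water-water,
#' solute-water and solute-solute interaction components (window mean minus
#' reference-window mean, per component). The components sum to `dH`
#' exactly on every row.
#'
#' @inheritParams enthalpy_profile
#' @return Data frame with columns `r`, `dE_ww`, `dE_aaw`, `dE_aaaa`,
#'   `dH`, per-component standard errors `se_ww`, `se_aaw`, `se_aaaa` and
#'   `se_dH`, ordered by `r`.
#' @export
enthalpy_components_profile <- function(windows, ref_center) {
  ws <- .window_energy_stats(windows, ref_center)
  s <- ws$stats
  ref <- s[ws$ref_idx, ]
  quad <- function(a, b) sqrt(a^2 + b^2)
  out <- data.frame(
    r = ws$centers,
    dE_ww = s[, "m_ww"] - ref["m_ww"],
    dE_aaw = s[, "m_aaw"] - ref["m_aaw"],
    dE_aaaa = s[, "m_aaaa"] - ref["m_aaaa"],
    se_ww = quad(s[, "se_ww"], ref["se_ww"]),
    se_aaw = quad(s[, "se_aaw"], ref["se_aaw"]),
    se_aaaa = quad(s[, "se_aaaa"], ref["se_aaaa"]),
    se_dH = quad(s[, "se_tot"], ref["se_tot"]))
  out$dH <- out$dE_ww + out$dE_aaw + out$dE_aaaa
  ## the reference window compared to itself is identically zero
  out[ws$ref_idx, c("dE_ww", "dE_aaw", "dE_aaaa", "dH")] <- 0
  out[ws$ref_idx, c("se_ww", "se_aaw", "se_aaaa", "se_dH")] <- 0
  rownames(out) <- NULL
  out[order(out$r), c("r", "dE_ww", "dE_aaw", "dE_aaaa", "dH",
                      "se_ww", "se_aaw", "se_aaaa", "se_dH")]
}

## internal: linear interpolation of a referenced PMF at coordinates r
.interp_pmf <- function(pmf, r) {
  stopifnot(inherits(pmf, "pmf_profile"))
  xs <- pmf$centers[pmf$defined]
  ys <- pmf$values[pmf$defined]
  if (any(r < min(xs) - 1e-12 | r > max(xs) + 1e-12))
    stop(sprintf(paste0("coordinate %.3f nm outside the defined PMF range ",
                        "[%.3f, %.3f] nm"),
                 r[which(r < min(xs) | r > max(xs))[1]], min(xs), max(xs)),
         call. = FALSE)
  approx(xs, ys, xout = r, rule = 2)$y
}

#' Entropy profile by subtraction
#'
#' The entropic term is defined by the decomposition identity:
#' `-T dS(r) = dG(r) - dH(r)`, with the free energy linearly interpolated
#' from the PMF bin centres to each window centre.
#'
#' @param pmf a referenced `pmf_profile` (anchored at the same reference
#'   coordinate used for the enthalpy).
#' @param enthalpy data frame from [enthalpy_profile()] (columns `r`, `dH`).
#' @return Data frame with columns `r`, `dG`, `dH`, `minus_TdS`.
#' @export
entropy_profile <- function(pmf, enthalpy) {
  if (is.null(pmf$reference))
    stop("PMF must be referenced before the entropy decomposition",
         call. = FALSE)
  ## at the reference coordinate the free energy is zero by definition;
  ## pin it rather than trusting centre-to-centre interpolation there
  ## (the reference may even sit just outside the bin-centre span)
  r <- enthalpy$r
  is_ref <- r == pmf$reference
  dg <- numeric(length(r))
  if (any(!is_ref)) dg[!is_ref] <- .interp_pmf(pmf, r[!is_ref])
  data.frame(r = enthalpy$r, dG = dg, dH = enthalpy$dH,
             minus_TdS = dg - enthalpy$dH)
}

#' Locate the surface free-energy minimum
#'
#' Finds the defined PMF bin with minimal free energy inside a region
#' (typically the interphase region around the Gibbs dividing surface).
#' Ties break toward smaller r; the result records whether the minimum is
#' interior to the region (a genuine surface well) or sits at a region
#' edge.
#'
#' @param pmf a `pmf_profile`.
#' @param region `c(lo, hi)` search interval, nm.
#' @return List with `r_min`, `dG_min`, `interior` (logical) and
#'   `bin_index`.
#' @export
find_surface_minimum <- function(pmf, region) {
  stopifnot(inherits(pmf, "pmf_profile"))
  if (!is.numeric(region) || length(region) != 2L || region[1] >= region[2])
    stop("'region' must be c(lo, hi) with lo < hi", call. = FALSE)
  in_region <- pmf$defined & pmf$centers >= region[1] &
    pmf$centers <= region[2]
  if (!any(in_region))
    stop(sprintf("no defined PMF bins inside the region [%g, %g] nm",
                 region[1], region[2]), call. = FALSE)
  cand <- which(in_region)
  best <- cand[which.min(pmf$values[cand])]   # which.min ties -> smaller r
  edge_bins <- range(cand)
  list(r_min = pmf$centers[best], dG_min = pmf$values[best],
       interior = !(best %in% edge_bins), bin_index = best)
}

#' Full decomposition record at the surface minimum
#'
#' Locates the PMF minimum inside `region`, takes the window nearest the
#' minimum, and assembles the free energy (interpolated from the PMF), the
#' enthalpy, the entropy term and the three interaction components into a
#' single record satisfying `dG = dH + minus_TdS` and
#' `dH = dE_ww + dE_aaw + dE_aaaa` exactly.
#'
#' @param pmf a referenced `pmf_profile`.
#' @param windows list of `umbrella_window` objects with energies.
#' @param ref_center bulk reference coordinate, nm.
#' @param region `c(lo, hi)` search interval for the minimum, nm.
#' @return A one-row data frame of class `decomposition_record` with
#'   columns `r`, `r_min`, `dG`, `dH`, `minus_TdS`, `dE_ww`, `dE_aaw`,
#'   `dE_aaaa`, `se_dH`, `interior`.
#' @export
decomposition_at_minimum <- function(pmf, windows, ref_center, region) {
  minimum <- find_surface_minimum(pmf, region)
  comp <- enthalpy_components_profile(windows, ref_center)
  i <- which.min(abs(comp$r - minimum$r_min))
  r_win <- comp$r[i]
  dg <- if (identical(r_win, pmf$reference)) 0 else .interp_pmf(pmf, r_win)
  rec <- data.frame(r = r_win, r_min = minimum$r_min, dG = dg,
                    dH = comp$dH[i], minus_TdS = dg - comp$dH[i],
                    dE_ww = comp$dE_ww[i], dE_aaw = comp$dE_aaw[i],
                    dE_aaaa = comp$dE_aaaa[i], se_dH = comp$se_dH[i],
                    interior = minimum$interior)
  class(rec) <- c("decomposition_record", class(rec))
  rec
}

#' Write a decomposition profile as CSV
#'
#' @param decomposition data frame combining [entropy_profile()] and
#'   [enthalpy_components_profile()] columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_decomposition <- function(decomposition, path) {
  write.csv(format(decomposition, digits = 12, trim = TRUE,
                   scientific = FALSE),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
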