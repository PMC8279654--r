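## minimum-image displacement vectors between position matrices (rows),
## orthorhombic box
.min_image <- function(disp, box) {
  for (k in 1:3) disp[, k] <- disp[, k] - box[k] * round(disp[, k] / box[k])
  disp
}

#' Number-density profile along the slab normal
#'
#' Bins selected atoms along z, averages counts over frames and divides by
#' the bin volume. The bulk density is estimated as the mean density within
#' `bulk_halfwidth` of the (density-weighted) slab centre, i.e. over the
#' central 2 nm of the slab by default.
#'
#' @param snapshots list of [snapshot()] objects.
#' @param selection residue name to select (e.g. `"SOL"`).
#' @param axis profile axis; only `"z"` is supported.
#' @param n_bins number of bins over `[0, box_z]`.
#' @param bulk_halfwidth half-width of the bulk estimation window, nm.
#' @return Object of class `density_profile`: `z_centers`, `density`
#'   (nm^-3), `bulk_density`, `bin_width`, `slab_center`, `n_frames`.
#' @export
density_profile <- function(snapshots, selection, axis = "z",
                            n_bins = 240L, bulk_halfwidth = 1) {
  axis <- match.arg(axis, "z")
  if (!is.list(snapshots) || length(snapshots) < 1L)
    stop("need at least one snapshot", call. = FALSE)
  if (!is.character(selection) || !nzchar(selection))
    stop("'selection' must be a nonempty residue name", call. = FALSE)
  n_bins <- .check_count(n_bins, "n_bins")
  box <- snapshots[[1]]$box
  bins <- .make_bins(0, box[3], n_bins)
  total <- numeric(n_bins)
  n_sel <- 0L
  for (s in snapshots) {
    z <- s$atoms$z[s$atoms$residue_name == selection]
    n_sel <- n_sel + length(z)
    idx <- .bin_index(z %% box[3], bins)
    total <- total + tabulate(idx[!is.na(idx)], nbins = n_bins)
  }
  if (n_sel == 0L)
    stop(sprintf("selection '%s' matches no atoms", selection),
         call. = FALSE)
  vol <- box[1] * box[2] * bins$width
  dens <- total / (length(snapshots) * vol)
  slab_center <- sum(bins$centers * dens) / sum(dens)
  in_bulk <- abs(bins$centers - slab_center) <= bulk_halfwidth
  structure(list(z_centers = bins$centers, density = dens,
                 bulk_density = mean(dens[in_bulk]),
                 bin_width = bins$width, slab_center = slab_center,
                 n_frames = length(snapshots)),
            class = "density_profile")
}

#' @export
print.density_profile <- function(x, ...) {
  cat(sprintf("Density profile: %d bins (width %.3g nm), bulk %.3f nm^-3, slab centre %.3f nm\n",
              length(x$z_centers), x$bin_width, x$bulk_density,
              x$slab_center))
  invisible(x)
}

#' Locate the Gibbs dividing surface
#'
#' Finds, on the outward flank of the slab (density decreasing away from
#' the slab centre), the point where the density crosses half its bulk
#' value, by linear interpolation between the bracketing bins.
#'
#' @param profile a [density_profile()].
#' @param side `"upper"` (z > slab centre) or `"lower"`.
#' @return Distance from the slab centre to the GDS, nm, with attributes
#'   `z_cross` (absolute z of the crossing) and `slab_center`.
#' @export
gibbs_dividing_surface <- function(profile, side = c("upper", "lower")) {
  stopifnot(inherits(profile, "density_profile"))
  side <- match.arg(side)
  half <- profile$bulk_density / 2
  zc <- profile$z_centers
  dens <- profile$density
  if (side == "upper") {
    ord <- which(zc >= profile$slab_center)
  } else {
    ord <- rev(which(zc <= profile$slab_center))
  }
  d <- dens[ord]
  below <- which(d < half)
  if (!length(below) || below[1] == 1L)
    stop("density never crosses half its bulk value on the outward flank: no interface found",
         call. = FALSE)
  j <- below[1]
  z1 <- zc[ord[j - 1L]]; z2 <- zc[ord[j]]
  d1 <- d[j - 1L]; d2 <- d[j]
  z_cross <- z1 + (half - d1) * (z2 - z1) / (d2 - d1)
  structure(abs(z_cross - profile$slab_center),
            z_cross = z_cross, slab_center = profile$slab_center)
}

#' Interphase region around the Gibbs dividing surface
#'
#' @param gds GDS position along the reaction coordinate, nm.
#' @param halfwidth half-width of the region, nm (> 0; default 0.6).
#' @return `c(lo, hi)` in nm.
#' @export
#' @examples
#' interphase_region(2.2, 0.6)   # [1.6, 2.8] nm
interphase_region <- function(gds, halfwidth = 0.6) {
  .check_scalar(gds, "gds")
  .check_scalar(halfwidth, "halfwidth", positive = TRUE)
  c(gds - halfwidth, gds + halfwidth)
}

#' Geometric hydrogen-bond criteria
#'
#' Distance and angular cutoffs for a geometric hydrogen bond. Because the
#' angular criterion is quoted in two conventions in the literature —
#' deviation of the donor-hydrogen-acceptor angle from linearity
#' (`angle_vertex = "hydrogen"`, i.e. D-H-A within 180 +/- cutoff) or the
#' hydrogen-donor-acceptor angle at the donor (`angle_vertex = "donor"`)
#' — both are supported; the hydrogen-vertex convention is the default.
#'
#' @param max_da_distance maximum donor-acceptor distance, nm (default
#'   0.35, i.e. 3.5 Angstrom).
#' @param max_angle_dev maximum angular deviation, degrees (default 30).
#' @param angle_vertex `"hydrogen"` or `"donor"`.
#' @return Object of class `hbond_criteria`.
#' @export
hbond_criteria <- function(max_da_distance = 0.35, max_angle_dev = 30,
                           angle_vertex = c("hydrogen", "donor")) {
  .check_scalar(max_da_distance, "max_da_distance", positive = TRUE)
  .check_scalar(max_angle_dev, "max_angle_dev", positive = TRUE)
  if (max_angle_dev > 180)
    stop("'max_angle_dev' must be <= 180 degrees", call. = FALSE)
  structure(list(max_da_distance = max_da_distance,
                 max_angle_dev = max_angle_dev,
                 angle_vertex = match.arg(angle_vertex)),
            class = "hbond_criteria")
}

## internal: angular deviations (deg) for donor/hydrogen/acceptor position
## matrices under a convention, with minimum-image displacements
.hbond_deviation <- function(pd, ph, pa, box, vertex) {
  if (vertex == "hydrogen") {
    ## deviation from linearity of the D-H-A angle
    v1 <- .min_image(pd - ph, box)
    v2 <- .min_image(pa - ph, box)
  } else {
    ## H-D-A angle at the donor
    v1 <- .min_image(ph - pd, box)
    v2 <- .min_image(pa - pd, box)
  }
  cosang <- rowSums(v1 * v2) /
    (sqrt(rowSums(v1^2)) * sqrt(rowSums(v2^2)))
  ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  if (vertex == "hydrogen") 180 - ang else ang
}

## internal: shared D-A pair enumeration; returns data frame of candidate
## triples with distances and deviations
.hbond_pairs <- function(snapshot, donors, hydrogens, acceptors,
                         max_da_distance, angle_vertex) {
  stopifnot(inherits(snapshot, "snapshot"))
  pos <- as.matrix(snapshot$atoms[, c("x", "y", "z")])
  box <- snapshot$box
  hyd <- as.matrix(hydrogens)
  if (ncol(hyd) != 2L)
    stop("'hydrogens' must be a two-column (donor, hydrogen) matrix",
         call. = FALSE)
  if (!all(hyd[, 1] %in% donors))
    stop("every hydrogen must map to exactly one listed donor",
         call. = FALSE)
  if (anyDuplicated(hyd[, 2]))
    stop("a hydrogen maps to more than one donor", call. = FALSE)
  out <- vector("list", nrow(hyd))
  for (i in seq_len(nrow(hyd))) {
    d_idx <- hyd[i, 1]; h_idx <- hyd[i, 2]
    acc <- acceptors[acceptors != d_idx]
    if (!length(acc)) next
    disp <- .min_image(pos[acc, , drop = FALSE] -
                         matrix(pos[d_idx, ], length(acc), 3, byrow = TRUE),
                       box)
    dist <- sqrt(rowSums(disp^2))
    keep <- dist <= max_da_distance
    if (!any(keep)) next
    acc <- acc[keep]; dist <- dist[keep]
    dev <- .hbond_deviation(
      matrix(pos[d_idx, ], length(acc), 3, byrow = TRUE),
      matrix(pos[h_idx, ], length(acc), 3, byrow = TRUE),
      pos[acc, , drop = FALSE], box, angle_vertex)
    out[[i]] <- data.frame(donor = d_idx, hydrogen = h_idx, acceptor = acc,
                           distance = dist, deviation = dev)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(data.frame(donor = integer(0), hydrogen = integer(0),
                      acceptor = integer(0), distance = numeric(0),
                      deviation = numeric(0)))
  do.call(rbind, out)
}

#' Count geometric hydrogen bonds in a snapshot
#'
#' Counts donor-hydrogen-acceptor triples satisfying the distance and
#' angular criteria, with donor != acceptor and minimum-image distances
#' under the orthorhombic box.
#'
#' @param snapshot a [snapshot()].
#' @param donors integer atom indices of donor heavy atoms.
#' @param hydrogens two-column matrix `(donor index, hydrogen index)`; each
#'   hydrogen maps to exactly one donor.
#' @param acceptors integer atom indices of acceptor heavy atoms.
#' @param criteria an [hbond_criteria()].
#' @return Integer bond count.
#' @export
count_hbonds <- function(snapshot, donors, hydrogens, acceptors,
                         criteria = hbond_criteria()) {
  stopifnot(inherits(criteria, "hbond_criteria"))
  pairs <- .hbond_pairs(snapshot, donors, hydrogens, acceptors,
                        criteria$max_da_distance, criteria$angle_vertex)
  sum(pairs$deviation <= criteria$max_angle_dev)
}

#' Mean hydrogen-bond count per umbrella window
#'
#' Frame-averaged geometric hydrogen-bond count for each window, indexed
#' by the window's reaction coordinate. Windows without snapshots are
#' excluded with a warning.
#'
#' @param per_window_snapshots named list: names are window coordinates r
#'   (nm, coercible to numeric), values are lists of [snapshot()]s.
#' @param selector function taking a snapshot and returning
#'   `list(donors, hydrogens, acceptors)`; defaults to
#'   [hbond_triplet_selection()].
#' @param criteria an [hbond_criteria()].
#' @return Data frame with columns `r` and `mean_count`, ordered by `r`.
#' @export
hbond_vs_r <- function(per_window_snapshots,
                       selector = hbond_triplet_selection,
                       criteria = hbond_criteria()) {
  if (!is.list(per_window_snapshots) || is.null(names(per_window_snapshots)))
    stop("'per_window_snapshots' must be a named list (names = r in nm)",
         call. = FALSE)
  r <- as.numeric(names(per_window_snapshots))
  if (any(is.na(r)))
    stop("names of 'per_window_snapshots' must be numeric coordinates",
         call. = FALSE)
  keep <- lengths(per_window_snapshots) > 0L
  if (!all(keep)) {
    warning(sprintf("excluding %d window(s) without snapshots: %s",
                    sum(!keep), paste(names(per_window_snapshots)[!keep],
                                      collapse = ", ")))
  }
  means <- vapply(per_window_snapshots[keep], function(snaps)
    mean(vapply(snaps, function(s) {
      sel <- selector(s)
      as.numeric(count_hbonds(s, sel$donors, sel$hydrogens, sel$acceptors,
                              criteria))
    }, numeric(1))), numeric(1))
  out <- data.frame(r = r[keep], mean_count = unname(means))
  out[order(out$r), ]
}

#' Orientation distribution over cos(theta)
#'
#' Normalises each vector, takes its z-component as the cosine of the
#' angle to the surface normal, and histograms over `[-1, 1]`. The result
#' is a probability density (integrates to one).
#'
#' @param vectors `n x 3` matrix of (not necessarily unit) vectors.
#' @param n_bins number of equal bins over `[-1, 1]`.
#' @return Object of class `orientation_histogram`: `edges`, `centers`,
#'   `density`, `n`.
#' @export
orientation_distribution <- function(vectors, n_bins = 20L) {
  v <- as.matrix(vectors)
  if (ncol(v) != 3L || nrow(v) < 1L || any(!is.finite(v)))
    stop("'vectors' must be a finite n x 3 matrix", call. = FALSE)
  n_bins <- .check_count(n_bins, "n_bins")
  norms <- sqrt(rowSums(v^2))
  if (any(norms == 0)) stop("zero vector in input", call. = FALSE)
  cost <- v[, 3] / norms
  bins <- .make_bins(-1, 1, n_bins)
  counts <- tabulate(.bin_index(cost, bins), nbins = n_bins)
  structure(list(edges = bins$edges, centers = bins$centers,
                 density = counts / (length(cost) * bins$width),
                 counts = counts, n = length(cost)),
            class = "orientation_histogram")
}

#' @export
print.orientation_histogram <- function(x, ...) {
  cat(sprintf("Orientation histogram: %d bins over cos(theta), %d vectors, mean cos %.3f\n",
              length(x$centers), x$n,
              sum(x$centers * x$counts) / x$n))
  invisible(x)
}

#' Intramolecular close pairs
#'
#' All unordered atom pairs within one residue at minimum-image distance
#' `<= cutoff`. If a bond topology is supplied, pairs separated by fewer
#' than `min_bond_separation` bonds are excluded (e.g. 2 removes directly
#' bonded 1-2 pairs). The result is sorted by distance.
#'
#' @param snapshot a [snapshot()].
#' @param residue_id residue to analyse.
#' @param cutoff distance cutoff, nm (default 0.35).
#' @param min_bond_separation minimum bonded-graph separation to keep a
#'   pair (0 keeps all pairs).
#' @param topology optional two-column matrix of bonded atom-index pairs
#'   (indices within the residue's atom ordering).
#' @return Data frame with columns `i`, `j` (atom indices within the
#'   snapshot), `distance` (nm), sorted by distance.
#' @export
close_pairs <- function(snapshot, residue_id, cutoff = 0.35,
                        min_bond_separation = 0L, topology = NULL) {
  stopifnot(inherits(snapshot, "snapshot"))
  .check_scalar(cutoff, "cutoff", positive = TRUE)
  sel <- which(snapshot$atoms$residue_id == residue_id)
  if (!length(sel))
    stop(sprintf("unknown residue id %s", residue_id), call. = FALSE)
  pos <- as.matrix(snapshot$atoms[sel, c("x", "y", "z")])
  n <- length(sel)
  empty <- data.frame(i = integer(0), j = integer(0), distance = numeric(0))
  if (n < 2L) return(empty)
  pr <- t(combn(n, 2L))
  disp <- .min_image(pos[pr[, 1], , drop = FALSE] -
                       pos[pr[, 2], , drop = FALSE], snapshot$box)
  dist <- sqrt(rowSums(disp^2))
  keep <- dist <= cutoff
  if (min_bond_separation > 0L && !is.null(topology)) {
    sep <- .bond_separation(n, topology)
    keep <- keep & sep[cbind(pr[, 1], pr[, 2])] >= min_bond_separation
  }
  if (!any(keep)) return(empty)
  out <- data.frame(i = sel[pr[keep, 1]], j = sel[pr[keep, 2]],
                    distance = dist[keep])
  out[order(out$distance), , drop = FALSE]
}

## all-pairs bonded-graph separations by BFS (small molecules only)
.bond_separation <- function(n, topology) {
  topo <- as.matrix(topology)
  adj <- vector("list", n)
  for (k in seq_len(nrow(topo))) {
    a <- topo[k, 1]; b <- topo[k, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  sep <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n); dist[s] <- 0
    queue <- s
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      for (v in adj[[u]]) if (dist[v] > dist[u] + 1) {
        dist[v] <- dist[u] + 1
        queue <- c(queue, v)
      }
    }
    sep[s, ] <- dist
  }
  sep
}

#' Donor-acceptor angular distribution
#'
#' For every donor-acceptor pair within the distance cutoff, records the
#' angular deviation under the configured convention and histograms it
#' over `[0, 180]` degrees. An empty result (no pairs in range) is a valid
#' empty histogram, not an error.
#'
#' @inheritParams count_hbonds
#' @param max_da_distance distance cutoff, nm.
#' @param angle_vertex `"hydrogen"` or `"donor"` (see [hbond_criteria()]).
#' @param n_bins histogram bins over `[0, 180]` degrees.
#' @return List with `angles` (deg), `edges`, `centers`, `density`
#'   (deg^-1; integrates to 1 when nonempty) and `n`.
#' @export
hda_angle_distribution <- function(snapshot, donors, hydrogens, acceptors,
                                   max_da_distance = 0.35,
                                   angle_vertex = c("hydrogen", "donor"),
                                   n_bins = 36L) {
  angle_vertex <- match.arg(angle_vertex)
  pairs <- .hbond_pairs(snapshot, donors, hydrogens, acceptors,
                        max_da_distance, angle_vertex)
  bins <- .make_bins(0, 180, .check_count(n_bins, "n_bins"))
  counts <- tabulate(.bin_index(pairs$deviation, bins),
                     nbins = length(bins$centers))
  dens <- if (nrow(pairs)) counts / (nrow(pairs) * bins$width)
          else counts * 0
  list(angles = pairs$deviation, edges = bins$edges,
       centers = bins$centers, density = dens, n = nrow(pairs))
}
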