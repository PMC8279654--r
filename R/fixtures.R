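#' Generate slab density snapshots
#'
#' Places single-site water-like particles so the expected number density
#' along z follows the smooth slab profile
#' \deqn{\rho(z) = \rho_b \cdot \tfrac12\,[1 - \tanh((|z - z_c| - z_{GDS}) /
#' w)],} i.e. bulk density inside the slab, half the bulk value exactly at
#' `gds_position` from the slab centre, and vanishing outside. Counts per
#' fine z-bin are Poisson; positions are uniform within the bin and in xy.
#'
#' @param slab_center slab centre along z, nm.
#' @param gds_position distance from the slab centre to the Gibbs dividing
#'   surface, nm (> 0).
#' @param interface_width tanh width of the interface, nm (> 0).
#' @param bulk_density bulk number density, nm^-3 (> 0).
#' @param box box lengths (nm).
#' @param n_frames number of independent snapshots.
#' @param seed integer RNG seed.
#' @param dz placement bin width along z, nm.
#' @return List of [snapshot()] objects (residue/atom names `SOL`/`OW`).
#' @export
#' @examples
#' snaps <- make_density_snapshots(6, 2, 0.3, 33, c(4, 4, 12), 5, seed = 1)
#' snaps[[1]]
make_density_snapshots <- function(slab_center, gds_position,
                                   interface_width, bulk_density,
                                   box = c(4, 4, 12), n_frames = 200L,
                                   seed = 1L, dz = 0.02) {
  .check_scalar(slab_center, "slab_center")
  .check_scalar(gds_position, "gds_position", positive = TRUE)
  .check_scalar(interface_width, "interface_width", positive = TRUE)
  .check_scalar(bulk_density, "bulk_density", positive = TRUE)
  n_frames <- .check_count(n_frames, "n_frames")
  if (!is.numeric(box) || length(box) != 3L || any(box <= 0))
    stop("'box' must be three positive lengths", call. = FALSE)
  if (slab_center - gds_position < 0 || slab_center + gds_position > box[3])
    stop(sprintf(paste0("box too small: slab at z = %g nm with GDS at ",
                        "+/- %g nm does not fit a %g nm box"),
                 slab_center, gds_position, box[3]), call. = FALSE)
  set.seed(.check_count(seed, "seed", min = -.Machine$integer.max))

  zc <- seq(dz / 2, box[3] - dz / 2, by = dz)
  rho <- bulk_density * 0.5 *
    (1 - tanh((abs(zc - slab_center) - gds_position) / interface_width))
  lambda <- rho * box[1] * box[2] * dz
  lapply(seq_len(n_frames), function(f) {
    counts <- rpois(length(lambda), lambda)
    n <- sum(counts)
    z <- rep(zc, counts) + runif(n, -dz / 2, dz / 2)
    snapshot(data.frame(residue_id = seq_len(n), residue_name = "SOL",
                        name = "OW",
                        x = runif(n, 0, box[1]), y = runif(n, 0, box[2]),
                        z = z, stringsAsFactors = FALSE),
             box, title = sprintf("slab frame %d", f))
  })
}

#' Generate a hydrogen-bond geometry fixture
#'
#' Builds one donor-hydrogen-acceptor triplet per requested geometry, with
#' exact donor-acceptor distance and exact angular deviation from linearity
#' of the D-H-A angle, placed at non-overlapping positions with random
#' global orientations. The donor-hydrogen bond length is 0.1 nm. Atoms are
#' named `OD` (donor), `HD1` (hydrogen) and `OA` (acceptor); each triplet
#' is one residue (`HBX`).
#'
#' @param geometries data frame or two-column matrix: donor-acceptor
#'   distance (nm, > 0.1) and angular deviation from linearity (degrees,
#'   in `[0, 180)`).
#' @param seed integer RNG seed.
#' @param spacing minimum separation between triplet sites, nm.
#' @return A [snapshot()] containing `3 * nrow(geometries)` atoms.
#' @seealso [hbond_triplet_selection()], [count_hbonds()]
#' @export
#' @examples
#' snap <- make_hbond_fixture(cbind(c(0.28, 0.40), c(0, 10)), seed = 1)
make_hbond_fixture <- function(geometries, seed = 1L, spacing = 1.5) {
  g <- as.matrix(geometries)
  if (ncol(g) != 2L || nrow(g) < 1L || any(!is.finite(g)))
    stop("'geometries' must be rows of (distance nm, deviation deg)",
         call. = FALSE)
  d <- g[, 1]; dev <- g[, 2]
  if (any(d <= 0.1))
    stop("donor-acceptor distances must exceed the 0.1 nm D-H bond length",
         call. = FALSE)
  if (any(dev < 0 | dev >= 180))
    stop("angular deviations must lie in [0, 180) degrees", call. = FALSE)
  ## feasibility of the D-H-A construction: with D-H = 0.1 nm the quadratic
  ## for the H-A arm must have a positive root
  disc <- d^2 - 0.01 * sin(dev * pi / 180)^2
  if (any(disc <= 0))
    stop("infeasible geometry: requested distance/deviation combination",
         call. = FALSE)
  set.seed(.check_count(seed, "seed", min = -.Machine$integer.max))

  n <- nrow(g)
  ## non-overlapping sites on a jittered cubic grid
  per_side <- ceiling(n^(1 / 3))
  box_len <- per_side * spacing + spacing
  idx <- seq_len(n) - 1L
  site <- cbind(idx %% per_side,
                (idx %/% per_side) %% per_side,
                idx %/% (per_side^2)) * spacing + spacing / 2 +
    matrix(runif(3 * n, -spacing * 0.1, spacing * 0.1), ncol = 3)

  rand_rotation <- function() {
    ## uniform random rotation from a normalized quaternion
    q <- rnorm(4); q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
             2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
             2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
           nrow = 3, byrow = TRUE)
  }

  atoms <- vector("list", n)
  for (i in seq_len(n)) {
    th <- dev[i] * pi / 180
    ## local frame: D at origin, H at (0,0,0.1); A along a direction making
    ## the D-H-A angle 180 - dev, i.e. H->A at angle dev from +z
    t_arm <- -0.1 * cos(th) + sqrt(0.01 * cos(th)^2 - 0.01 + d[i]^2)
    local <- rbind(D = c(0, 0, 0),
                   H = c(0, 0, 0.1),
                   A = c(t_arm * sin(th), 0, 0.1 + t_arm * cos(th)))
    rot <- rand_rotation()
    pos <- local %*% t(rot) + matrix(site[i, ], 3, 3, byrow = TRUE)
    atoms[[i]] <- data.frame(residue_id = i, residue_name = "HBX",
                             name = c("OD", "HD1", "OA"),
                             x = pos[, 1], y = pos[, 2], z = pos[, 3],
                             stringsAsFactors = FALSE)
  }
  snapshot(do.call(rbind, atoms), box = rep(box_len, 3),
           title = "hydrogen-bond fixture (synthetic)")
}

#' Standard selections for [make_hbond_fixture()] snapshots
#'
#' @param snap a fixture snapshot.
#' @return List with `donors`, `acceptors` (atom indices) and `hydrogens`
#'   (two-column matrix of donor index, hydrogen index) as expected by
#'   [count_hbonds()].
#' @export
hbond_triplet_selection <- function(snap) {
  stopifnot(inherits(snap, "snapshot"))
  a <- snap$atoms
  donors <- which(a$name == "OD")
  hydro <- which(a$name == "HD1")
  ## pair donor and hydrogen through the shared residue id
  m <- match(a$residue_id[hydro], a$residue_id[donors])
  list(donors = donors, acceptors = which(a$name == "OA"),
       hydrogens = cbind(donor = donors[m], hydrogen = hydro))
}

#' Generate unit-vector orientation fixtures
#'
#' @param mode `"aligned"` (all along +z), `"planar"` (all in the xy-plane)
#'   or `"isotropic"` (uniform on the unit sphere).
#' @param n number of vectors (>= 1).
#' @param seed integer RNG seed.
#' @return An `n x 3` matrix of unit vectors.
#' @export
#' @examples
#' v <- make_orientation_fixture("isotropic", 1000, seed = 1)
make_orientation_fixture <- function(mode = c("aligned", "planar",
                                              "isotropic"),
                                     n, seed = 1L) {
  mode <- match.arg(mode)
  n <- .check_count(n, "n")
  set.seed(.check_count(seed, "seed", min = -.Machine$integer.max))
  switch(mode,
    aligned = matrix(rep(c(0, 0, 1), each = n), ncol = 3),
    planar = {
      phi <- runif(n, 0, 2 * pi)
      cbind(cos(phi), sin(phi), 0)
    },
    isotropic = {
      v <- matrix(rnorm(3 * n), ncol = 3)
      v / sqrt(rowSums(v^2))
    })
}
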