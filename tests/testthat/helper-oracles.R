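## Independent oracles and small fixture builders used across the suite.

kB <- boltzmann_kJmolK()

## plainly written re-evaluation of the landscape closed form, kept
## independent of the package's vectorized implementation
oracle_pmf <- function(r, p) {
  vapply(r, function(ri) {
    gauss <- (ri - p$well_center) / p$well_width
    well <- -p$well_depth * exp(-0.5 * gauss * gauss)
    wall <- exp((ri - p$wall_position) / p$wall_scale)
    well + wall
  }, numeric(1))
}

oracle_switch <- function(r, p) {
  vapply(r, function(ri) {
    u <- (ri - p$switch_center) / p$switch_width
    exp(u) / (1 + exp(u))
  }, numeric(1))
}

## brute-force O(n^2) hydrogen-bond recount: explicit loops, scalar
## minimum image, law-of-cosines-free angle evaluation
brute_hbond_count <- function(snap, donors, hydrogens, acceptors,
                              criteria) {
  pos <- as.matrix(snap$atoms[, c("x", "y", "z")])
  box <- snap$box
  mi <- function(v) v - box * round(v / box)
  ang_dev <- function(d, h, a) {
    if (criteria$angle_vertex == "hydrogen") {
      v1 <- mi(d - h); v2 <- mi(a - h)
      th <- acos(max(-1, min(1, sum(v1 * v2) /
                               sqrt(sum(v1^2) * sum(v2^2)))))
      180 - th * 180 / pi
    } else {
      v1 <- mi(h - d); v2 <- mi(a - d)
      acos(max(-1, min(1, sum(v1 * v2) /
                         sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
    }
  }
  n <- 0L
  for (k in seq_len(nrow(hydrogens))) {
    d_i <- hydrogens[k, 1]; h_i <- hydrogens[k, 2]
    for (a_i in acceptors) {
      if (a_i == d_i) next
      dv <- mi(pos[a_i, ] - pos[d_i, ])
      if (sqrt(sum(dv^2)) > criteria$max_da_distance) next
      if (ang_dev(pos[d_i, ], pos[h_i, ], pos[a_i, ]) <=
            criteria$max_angle_dev)
        n <- n + 1L
    }
  }
  n
}

## brute-force close-pair recount within a residue
brute_close_pairs <- function(snap, residue_id, cutoff) {
  sel <- which(snap$atoms$residue_id == residue_id)
  pos <- as.matrix(snap$atoms[sel, c("x", "y", "z")])
  box <- snap$box
  out <- NULL
  if (length(sel) >= 2) {
    for (i in 1:(length(sel) - 1)) for (j in (i + 1):length(sel)) {
      v <- pos[i, ] - pos[j, ]
      v <- v - box * round(v / box)
      d <- sqrt(sum(v^2))
      if (d <= cutoff) out <- rbind(out, c(sel[i], sel[j], d))
    }
  }
  if (is.null(out)) return(data.frame(i = integer(0), j = integer(0),
                                      distance = numeric(0)))
  out <- data.frame(i = out[, 1], j = out[, 2], distance = out[, 3])
  out[order(out$distance), ]
}

## umbrella window with exact iid Gaussian coordinates (the biased
## Boltzmann distribution on a flat landscape), bypassing the integrator
gaussian_window <- function(center, spring, n, temperature = 300,
                            seed = 1) {
  set.seed(seed)
  structure(list(center = center, spring = spring,
                 time = seq_len(n) * 1.0,
                 samples = rnorm(n, center, sqrt(kB * temperature / spring)),
                 energies = NULL, label = sprintf("g%.2f", center),
                 seed = seed),
            class = "umbrella_window")
}

## window with synthetic energies but arbitrary coordinates, for the
## decomposition identity and standard-error tests
energy_window <- function(center, n, means = c(0, 0, 0), noise = 1,
                          seed = 1) {
  set.seed(seed)
  e_ww <- means[1] + rnorm(n, sd = noise)
  e_aaw <- means[2] + rnorm(n, sd = noise)
  e_aaaa <- means[3] + rnorm(n, sd = noise)
  structure(list(center = center, spring = 1000,
                 time = seq_len(n) * 1.0, samples = rep(center, n),
                 energies = data.frame(e_ww = e_ww, e_aaw = e_aaw,
                                       e_aaaa = e_aaaa,
                                       e_total = e_ww + e_aaw + e_aaaa),
                 label = sprintf("e%.2f", center), seed = seed),
            class = "umbrella_window")
}

## expected bin probabilities for a Boltzmann density on [lo, hi],
## integrated by Simpson's rule per bin
boltzmann_bin_probs <- function(pot, lo, hi, n_bins, temperature = 300,
                                n_sub = 51) {
  edges <- seq(lo, hi, length.out = n_bins + 1)
  w <- vapply(seq_len(n_bins), function(j) {
    x <- seq(edges[j], edges[j + 1], length.out = n_sub)
    y <- exp(-true_pmf(x, pot) / (kB * temperature))
    h <- x[2] - x[1]
    h / 3 * (y[1] + y[n_sub] + 4 * sum(y[seq(2, n_sub - 1, by = 2)]) +
               2 * sum(y[seq(3, n_sub - 2, by = 2)]))
  }, numeric(1))
  w / sum(w)
}

## small pipeline configuration for orchestration tests
tiny_config <- function(dir, seed = 1, ...) {
  pipeline_config(master_seed = seed, n_steps = 2e4, stride = 10L,
                  equil_steps = 1000L, output_dir = dir,
                  slab = list(n_frames = 20L),
                  orientation_n = 2000L, ...)
}
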