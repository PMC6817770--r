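# Shared fixtures, all built in code.

# circular annulus spec: lumen radius r, wall thickness t (micrometers)
annulus_spec <- function(r, t, rotation = 0, seed = 1L, ...) {
  vessel_spec(c(r, r), wall_thickness_base = t, rotation = rotation,
              seed = seed, ...)
}

# hand-built rectangular vessel: k x k lumen block inside a wall frame of
# given width, centered in a grid with a background margin
block_vessel <- function(lumen_side, wall_width = 2L, margin = 2L,
                         microns_per_pixel = 1, ...) {
  n <- lumen_side + 2L * (wall_width + margin)
  lab <- matrix(0L, n, n)
  w0 <- margin + 1L; w1 <- n - margin
  lab[w0:w1, w0:w1] <- 2L
  l0 <- margin + wall_width + 1L; l1 <- n - margin - wall_width
  lab[l0:l1, l0:l1] <- 1L
  segmented_vessel(lab, microns_per_pixel, ...)
}

# rotate a label matrix by 90 degrees
rot90 <- function(m) t(m)[, nrow(m):1, drop = FALSE]

# independent brute-force Mann-Whitney oracle: full enumeration over combn()
# of which pooled positions belong to sample 1
brute_mwu_p <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  n <- length(pooled)
  rk <- rank(pooled)
  u_obs <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(n, n1)
  us <- apply(combs, 2L, function(ix) sum(rk[ix]) - n1 * (n1 + 1) / 2)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}
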