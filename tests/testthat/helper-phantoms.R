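# Shared fixtures: all synthetic, built in code at test time.

# a small phantom stack for quick tests
small_phantom <- function(shape = c(80, 32, 32), seed = 101, n_bodies = 8) {
  generate_phantom(phantom_spec(shape = shape, seed = seed,
                                n_bodies = n_bodies))
}

# cut one phantom into a bottom and a top acquisition with true overlap `o`
# and exact (or deliberately corrupted) motor metadata
split_two <- function(phantom, o, n_bottom = NULL, motor_error_slices = 0L,
                      gain = 1, offset = 0, noise_sigma = 0,
                      seed_noise = 1L) {
  nz <- n_slices(phantom)
  if (is.null(n_bottom)) n_bottom <- ceiling((nz + o) / 2)
  z_top <- n_bottom - o
  sims <- list(
    acquisition_sim(0L, n_bottom, seed = seed_noise,
                    noise_sigma = noise_sigma),
    acquisition_sim(z_top, nz - z_top, gain = gain, offset = offset,
                    noise_sigma = noise_sigma,
                    motor_error_slices = motor_error_slices,
                    seed = seed_noise + 1L))
  sim <- simulate_acquisitions(phantom, sims)
  list(bottom = sim$acquisitions[[1]]$stack,
       top = sim$acquisitions[[2]]$stack,
       meta_bottom = sim$acquisitions[[1]]$meta,
       meta_top = sim$acquisitions[[2]]$meta,
       true_overlap = sim$truth$true_overlap_slices[1])
}

# --- independent oracles -------------------------------------------------

# Gaussian kernel by direct formula (independent of the package internals)
oracle_gaussian_kernel <- function(sigma, max_size = Inf) {
  r <- ceiling(3 * sigma)
  if (2 * r + 1 > max_size) r <- (max_size - 1) %/% 2
  g <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

# brute-force 2D convolution with edge replication, O(n^2 k^2) loops
oracle_conv_replicate <- function(img, kern) {
  nr <- nrow(img); nc <- ncol(img)
  kr <- (nrow(kern) - 1) / 2; kc <- (ncol(kern) - 1) / 2
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    acc <- 0
    for (a in -kr:kr) for (b in -kc:kc) {
      ii <- min(max(i + a, 1), nr)
      jj <- min(max(j + b, 1), nc)
      acc <- acc + img[ii, jj] * kern[a + kr + 1, b + kc + 1]
    }
    out[i, j] <- acc
  }
  out
}

oracle_highpass <- function(img, sigma) {
  k <- oracle_gaussian_kernel(sigma, max_size = min(dim(img)))
  img - oracle_conv_replicate(img, k)
}

oracle_sd_pop <- function(x) sqrt(sum((x - mean(x))^2) / length(x))

# exhaustive refinement: score every feasible bottom index (no window) with
# the same tie-break (closest to coarse, then smaller index); checks that
# the windowed search loses nothing when the truth lies inside the window
oracle_exhaustive_refine <- function(bottom, top, coarse, sigma = 4) {
  nb <- n_slices(bottom); nt <- n_slices(top)
  ref <- (coarse - 1) %/% 2
  refimg <- get_slice(top, ref + 1)
  js <- 0:(nb - 1)
  js <- js[nb - js + ref >= 1 & nb - js + ref <= min(nb, nt)]
  scores <- vapply(js, function(j)
    match_score(refimg, get_slice(bottom, j + 1), sigma), 0)
  smin <- min(scores)
  tied <- which(scores == smin)
  if (length(tied) > 1) {
    dist <- abs((nb - js[tied] + ref) - coarse)
    tied <- tied[dist == min(dist)]
    tied <- tied[which.min(js[tied])]
  }
  nb - js[tied[1]] + ref
}
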