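# Shared fixtures and independent oracles for the test suite.

# Quiet imaging defaults used across tests; noise-free variant for geometry.
img_noisy <- function(seed = 1L) imaging_spec(seed = seed)
img_clean <- function(seed = 1L) imaging_spec(seed = seed, noise = FALSE)

top_image <- function(offset = 0, seed = 1L, noise = TRUE, ...) {
  generate_top_view(centriole_spec("top", protein_offset_nm = offset, ...),
                    if (noise) img_noisy(seed) else img_clean(seed))
}

# Pooled per-spoke offsets over a batch of preset top views.
pooled_offsets <- function(preset, channel, n, seed) {
  sim <- simulate_centrioles(preset, n = n, view = "top",
                             channel = channel, seed = seed)
  unlist(lapply(sim$images, function(img) {
    ctr <- find_center(img)
    res <- measure_triplet_offsets(extract_spokes(img, ctr))
    res$offsets$delta_nm[res$offsets$resolved]
  }))
}

# Lateral-view length + coverage measurements over a preset batch.
lateral_measurements <- function(preset, channel, n, seed) {
  sim <- simulate_centrioles(preset, n = n, view = "lateral",
                             channel = channel, seed = seed)
  out <- t(vapply(sim$images, function(img) {
    ap <- axial_profile(img)
    lt <- measure_length(ap, "tubulin")
    lp <- measure_length(ap, "protein")
    cv <- coverage_and_position(lt, lp)
    c(tubulin = lt$length_nm, protein = lp$length_nm,
      coverage = cv$coverage_pct, position = cv$position_pct)
  }, numeric(4)))
  list(measured = as.data.frame(out), manifest = sim$manifest)
}

# Independent Mann-Whitney oracle: U by direct pairwise comparison and
# two-sided p by exhaustive enumeration of labelings (no ranks involved).
oracle_mw_p <- function(a, b) {
  u_of <- function(x, y) {
    sum(vapply(x, function(xi) sum(xi > y) + 0.5 * sum(xi == y), 0))
  }
  pool <- c(a, b)
  n <- length(pool); na <- length(a)
  u_obs <- u_of(a, b)
  idx <- utils::combn(n, na)
  us <- apply(idx, 2, function(ii) u_of(pool[ii], pool[-ii]))
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# Independent Fisher oracle: enumerate all tables with the observed margins
# via the hypergeometric mass; sum probabilities <= observed.
oracle_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1]); n <- sum(tab)
  dh <- function(a) stats::dhyper(a, r1, r2, c1)
  p_obs <- dh(tab[1, 1])
  a_range <- max(0, c1 - r2):min(r1, c1)
  sum(dh(a_range)[dh(a_range) <= p_obs * (1 + 1e-7)])
}
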