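# Independent oracles used by the tests: closed-form diffusion reflectance,
# brute-force rank-test enumeration, permutation generation.

# All permutations of 1..n (n small)
perms <- function(n) {
  if (n == 1) return(matrix(1))
  p <- perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) cbind(k, p + (p >= k))))
}

# Exact Wilcoxon rank-sum by enumeration of all group assignments
bf_wilcox <- function(x, y) {
  m <- length(x); n <- length(y); z <- c(x, y)
  idx <- utils::combn(m + n, m)
  U <- apply(idx, 2, function(i) {
    xx <- z[i]; yy <- z[-i]
    sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
  })
  u <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  list(statistic = u,
       p.value = min(1, 2 * min(mean(U <= u), mean(U >= u))))
}

# Exact Spearman correlation by enumeration of all rank permutations
bf_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y); n <- length(x)
  S <- sum((rx - ry)^2)
  pm <- perms(n)
  Sperm <- apply(pm, 1, function(p) sum((rx - ry[p])^2))
  list(rho = 1 - 6 * S / (n * (n^2 - 1)),
       p.value = min(1, 2 * min(mean(Sperm <= S), mean(Sperm >= S))))
}

# Farrell-style dipole diffusion-theory reflectance per unit area at radius
# rho (mm) from a pencil source, matched-index boundary
diffusion_reflectance <- function(rho_mm, mua, musp) {
  mua <- mua / 10; musp <- musp / 10        # mm^-1
  mutr <- mua + musp
  z0 <- 1 / mutr
  zb <- 2 / (3 * mutr)                       # A = 1, matched index
  mueff <- sqrt(3 * mua * mutr)
  r1 <- sqrt(z0^2 + rho_mm^2)
  r2 <- sqrt((z0 + 2 * zb)^2 + rho_mm^2)
  (1 / (4 * pi)) * (z0 * (mueff + 1 / r1) * exp(-mueff * r1) / r1^2 +
    (z0 + 2 * zb) * (mueff + 1 / r2) * exp(-mueff * r2) / r2^2)
}

# Linear kinetics data for hand-built cohorts
make_series <- function(site_id, intercept, slope, times, histology = "adipose",
                        diagnosis = "benign", specimen = "lumpectomy",
                        noise_sd = 0, endpoint = "THb") {
  v <- intercept + slope * times
  if (noise_sd > 0) v <- v + stats::rnorm(length(times), 0, noise_sd)
  d <- data.frame(site_id = site_id, specimen_type = specimen,
                  histology = histology, diagnosis = diagnosis,
                  time_min = times)
  d[[endpoint]] <- v
  d
}
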