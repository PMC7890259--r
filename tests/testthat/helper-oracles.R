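# Independent oracles used to validate the package's own implementations.

# Connected-component labeling by iterative minimum-label propagation:
# completely different algorithm from the package's stack-based flood fill.
oracle_label_components <- function(mask, connectivity) {
  d <- dim(mask)
  offs <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  manh <- abs(offs$di) + abs(offs$dj) + abs(offs$dk)
  offs <- offs[manh > 0 & manh <= switch(as.character(connectivity),
                                         "6" = 1, "18" = 2, "26" = 3), ]
  lab <- array(seq_along(mask), d)
  lab[!mask] <- 0L
  repeat {
    old <- lab
    for (o in seq_len(nrow(offs))) {
      a <- offs$di[o]; b <- offs$dj[o]; c0 <- offs$dk[o]
      ix <- seq_len(d[1]); jx <- seq_len(d[2]); kx <- seq_len(d[3])
      dst_i <- ix[ix + a >= 1 & ix + a <= d[1]]
      dst_j <- jx[jx + b >= 1 & jx + b <= d[2]]
      dst_k <- kx[kx + c0 >= 1 & kx + c0 <= d[3]]
      src <- lab[dst_i + a, dst_j + b, dst_k + c0, drop = FALSE]
      cur <- lab[dst_i, dst_j, dst_k, drop = FALSE]
      upd <- cur > 0 & src > 0 & src < cur
      cur[upd] <- src[upd]
      lab[dst_i, dst_j, dst_k] <- cur
    }
    if (identical(lab, old)) break
  }
  # renumber components in scan order of their first voxel
  ids <- unique(lab[lab > 0])
  first <- vapply(ids, function(i) min(which(lab == i)), integer(1))
  ids <- ids[order(first)]
  out <- array(0L, d)
  for (r in seq_along(ids)) out[lab == ids[r]] <- r
  out
}

# Brute-force pairwise-concordance AUC (ties count half).
oracle_auc <- function(prob, labels) {
  pos <- prob[labels == "B"]
  neg <- prob[labels == "A"]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# Exact binomial upper tail by direct enumeration; exact rational arithmetic
# in doubles for chance = 1/2 and n <= 20 (integer numerators below 2^53).
oracle_binom_upper <- function(k, n, chance = 0.5) {
  if (k <= 0) return(1)
  j <- k:n
  if (chance == 0.5) sum(choose(n, j)) / 2^n
  else sum(choose(n, j) * chance^j * (1 - chance)^(n - j))
}

# Small cohort built directly from arrays (no generator) for plumbing tests.
make_cohort <- function(vols, mask = NULL, groups = NULL, ages = NULL,
                        genders = NULL, voxel_mm = 1.5) {
  n <- dim(vols)[4]
  grid <- dim(vols)[1:3]
  if (is.null(mask)) mask <- array(TRUE, grid)
  if (is.null(groups)) groups <- rep(c("A", "B"), length.out = n)
  if (is.null(ages)) ages <- seq(30, 60, length.out = n)
  if (is.null(genders)) genders <- rep(c("M", "F"), length.out = n)
  aff <- diag(c(voxel_mm, voxel_mm, voxel_mm, 1))
  aff[1:3, 4] <- -voxel_mm * (grid - 1) / 2
  cohort_volumes(vols, mask, aff,
                 data.frame(id = sprintf("S%03d", seq_len(n)), group = groups,
                            age = ages, gender = genders),
                 check_nonnegative = FALSE)
}

# Cohort of pure-noise volumes around a constant baseline.
noise_cohort <- function(grid = c(8, 8, 8), n_a = 4, n_b = 4, sd = 0.1,
                         base = 0.5, seed = 1) {
  set.seed(seed)
  n <- n_a + n_b
  vols <- array(base + rnorm(prod(grid) * n, 0, sd), c(grid, n))
  make_cohort(vols, groups = rep(c("A", "B"), c(n_a, n_b)))
}
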