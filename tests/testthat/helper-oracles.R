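# Independent brute-force oracles. These deliberately use naive enumeration,
# never the package's builders.

ORACLE_OFFSETS <- {
  o <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  o <- o[!(o$dx == 0 & o$dy == 0 & o$dz == 0), ]
  half <- o[o$dx > 0 | (o$dx == 0 & o$dy > 0) | (o$dx == 0 & o$dy == 0 & o$dz > 0), ]
  as.matrix(half)
}

# merged symmetric GLCM by exhaustive ordered-pair enumeration over the full
# 26-neighbourhood (equivalent to both-direction counting over 13 offsets)
oracle_glcm <- function(levels, nb) {
  dm <- dim(levels)
  M <- matrix(0, nb, nb)
  for (z in 1:dm[3]) for (y in 1:dm[2]) for (x in 1:dm[1]) {
    li <- levels[x, y, z]
    if (li == 0L) next
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      x2 <- x + dx; y2 <- y + dy; z2 <- z + dz
      if (x2 < 1 || x2 > dm[1] || y2 < 1 || y2 > dm[2] || z2 < 1 || z2 > dm[3]) next
      lj <- levels[x2, y2, z2]
      if (lj > 0L) M[li, lj] <- M[li, lj] + 1
    }
  }
  M
}

oracle_glrlm <- function(levels, nb) {
  dm <- dim(levels)
  maxlen <- max(dm)
  M <- matrix(0, nb, maxlen)
  inb <- function(v) all(v >= 1 & v <= dm)
  for (o in seq_len(nrow(ORACLE_OFFSETS))) {
    d <- ORACLE_OFFSETS[o, ]
    for (z in 1:dm[3]) for (y in 1:dm[2]) for (x in 1:dm[1]) {
      v <- c(x, y, z)
      li <- levels[x, y, z]
      if (li == 0L) next
      prev <- v - d
      if (inb(prev) && levels[prev[1], prev[2], prev[3]] == li) next
      len <- 1L
      nxt <- v + d
      while (inb(nxt) && levels[nxt[1], nxt[2], nxt[3]] == li) {
        len <- len + 1L
        nxt <- nxt + d
      }
      M[li, len] <- M[li, len] + 1
    }
  }
  M[, seq_len(max(c(1, which(colSums(M) > 0)))), drop = FALSE]
}

oracle_glszm <- function(levels, nb) {
  dm <- dim(levels)
  seen <- array(FALSE, dm)
  zones <- list()
  for (start in which(levels > 0L & !seen)) {
    if (seen[start]) next
    lev <- levels[start]
    stack <- start
    seen[start] <- TRUE
    size <- 0L
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      size <- size + 1L
      ijk <- arrayInd(v, dm)
      for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
        if (dx == 0 && dy == 0 && dz == 0) next
        w <- ijk + c(dx, dy, dz)
        if (any(w < 1) || any(w > dm)) next
        wi <- w[1] + dm[1] * (w[2] - 1) + dm[1] * dm[2] * (w[3] - 1)
        if (!seen[wi] && levels[wi] == lev) { seen[wi] <- TRUE; stack <- c(stack, wi) }
      }
    }
    zones[[length(zones) + 1L]] <- c(lev, size)
  }
  maxs <- max(vapply(zones, `[`, 0, 2))
  M <- matrix(0, nb, maxs)
  for (zn in zones) M[zn[1], zn[2]] <- M[zn[1], zn[2]] + 1
  M
}

oracle_ngtdm <- function(levels, nb) {
  dm <- dim(levels)
  M <- matrix(0, nb, 2)
  for (z in 1:dm[3]) for (y in 1:dm[2]) for (x in 1:dm[1]) {
    li <- levels[x, y, z]
    if (li == 0L) next
    nbrs <- c()
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      x2 <- x + dx; y2 <- y + dy; z2 <- z + dz
      if (x2 < 1 || x2 > dm[1] || y2 < 1 || y2 > dm[2] || z2 < 1 || z2 > dm[3]) next
      lj <- levels[x2, y2, z2]
      if (lj > 0L) nbrs <- c(nbrs, lj)
    }
    if (length(nbrs)) {
      M[li, 1] <- M[li, 1] + 1
      M[li, 2] <- M[li, 2] + abs(li - mean(nbrs))
    }
  }
  M
}

# AUC by exhaustive concordant-pair counting
oracle_auc <- function(values, labels) {
  pos <- values[labels == 1]
  neg <- values[labels == 0]
  s <- 0
  for (a in pos) for (b in neg) s <- s + (a > b) + 0.5 * (a == b)
  a <- s / (length(pos) * length(neg))
  max(a, 1 - a)
}

# Youden scan over every candidate threshold (all midpoints plus the two
# boundary thresholds)
oracle_youden <- function(scores, labels) {
  su <- sort(unique(scores))
  half <- (max(su) - min(su) + 1) / 2
  cands <- c(if (length(su) > 1) (su[-1] + su[-length(su)]) / 2,
             min(su) - half, max(su) + half)
  best_yi <- -Inf; best_c <- -Inf
  for (cc in cands) {
    se <- mean(scores[labels == 1] >= cc)
    sp <- mean(scores[labels == 0] < cc)
    yi <- se + sp - 1
    if (yi > best_yi + 1e-12 || (abs(yi - best_yi) <= 1e-12 && cc > best_c)) {
      best_yi <- yi; best_c <- cc
    }
  }
  list(cutoff = best_c, youden = best_yi)
}

random_level_grid <- function(max_dim = 8L, nb = NULL) {
  dm <- sample(2:max_dim, 3, replace = TRUE)
  if (is.null(nb)) nb <- sample(2:6, 1)
  lev <- array(sample(0:nb, prod(dm), replace = TRUE, # 0 = out of mask
                      prob = c(0.3, rep(0.7 / nb, nb))), dm)
  if (all(lev == 0L)) lev[1] <- 1L
  list(levels = lev, nb = nb)
}

make_ball_mask <- function(r, spacing = c(1, 1, 1)) {
  d <- 2L * r + 5L
  c0 <- (d + 1) / 2
  g <- expand.grid(x = 1:d, y = 1:d, z = 1:d)
  m <- array(as.integer((g$x - c0)^2 + (g$y - c0)^2 + (g$z - c0)^2 <= r^2),
             c(d, d, d))
  roi_mask(m, spacing = spacing)
}

small_test_cohort_config <- function(...) {
  args <- list(n_train = 20L, n_test = 16L, prevalence = 0.25,
               grid_dim = c(32L, 32L, 24L))
  do.call(cohort_config, utils::modifyList(args, list(...)))
}
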