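# Independent oracles used across test files. Each deliberately takes a
# different algorithmic route from the implementation it checks.

# Horn's closed-form quaternion solution for the optimal proper rotation;
# checks the SVD-based Kabsch fit by a different decomposition entirely.
horn_rmsd <- function(X, Y) {
  n <- nrow(X)
  Xc <- sweep(X, 2, colMeans(X))
  Yc <- sweep(Y, 2, colMeans(Y))
  S <- t(Yc) %*% Xc
  N <- matrix(c(
    S[1,1]+S[2,2]+S[3,3], S[2,3]-S[3,2],        S[3,1]-S[1,3],        S[1,2]-S[2,1],
    S[2,3]-S[3,2],        S[1,1]-S[2,2]-S[3,3], S[1,2]+S[2,1],        S[3,1]+S[1,3],
    S[3,1]-S[1,3],        S[1,2]+S[2,1],       -S[1,1]+S[2,2]-S[3,3], S[2,3]+S[3,2],
    S[1,2]-S[2,1],        S[3,1]+S[1,3],        S[2,3]+S[3,2],       -S[1,1]-S[2,2]+S[3,3]
  ), 4, 4, byrow = TRUE)
  lambda <- max(eigen(N, symmetric = TRUE, only.values = TRUE)$values)
  sqrt(max(0, (sum(Xc^2) + sum(Yc^2) - 2 * lambda)) / n)
}

# exhaustive gapless placement scan by direct substring comparison
offset_scan_oracle <- function(frag, refseq) {
  m <- nchar(frag); n <- nchar(refseq)
  if (m > n) return(NULL)
  best <- list(offset = NA, matches = -1)
  for (off in 1:(n - m + 1)) {
    win <- substr(refseq, off, off + m - 1)
    matches <- sum(strsplit(frag, "")[[1]] == strsplit(win, "")[[1]])
    if (matches > best$matches) best <- list(offset = off, matches = matches)
  }
  best
}

# connected components by BFS over a thresholded identity graph (independent
# of the union-find single-linkage in the package)
bfs_cluster_count <- function(rows, idx, theta) {
  k <- length(idx)
  if (k == 0) return(0L)
  ident <- function(a, b) {
    any_res <- a != "-" | b != "-"
    sum(a == b & a != "-") / max(1, sum(any_res))
  }
  adj <- matrix(FALSE, k, k)
  for (a in seq_len(k)) for (b in seq_len(k)) {
    adj[a, b] <- ident(rows[idx[a], ], rows[idx[b], ]) >= theta
  }
  seen <- rep(FALSE, k); comps <- 0L
  for (s in seq_len(k)) {
    if (seen[s]) next
    comps <- comps + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (seen[v]) next
      seen[v] <- TRUE
      queue <- c(queue, which(adj[v, ] & !seen))
    }
  }
  comps
}

# rigid motion helpers for invariance tests
random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1-2*(y^2+z^2), 2*(x*y-w*z),   2*(x*z+w*y),
    2*(x*y+w*z),   1-2*(x^2+z^2), 2*(y*z-w*x),
    2*(x*z-w*y),   2*(y*z+w*x),   1-2*(x^2+y^2)
  ), 3, 3, byrow = TRUE)
}

apply_rigid <- function(M, R, t) M %*% t(R) + matrix(t, nrow(M), 3, byrow = TRUE)

rigid_move_structure <- function(sf, R, t) {
  for (ch in names(sf$protein_chains)) {
    sf$protein_chains[[ch]] <-
      transform_structure(sf$protein_chains[[ch]], R, t)
  }
  sf
}

# 3-class string from MDAnalysis DSSP (pydssp port), frozen at development
# time as the external reference assignment for the default fixtures:
# make_backbone(20, "helix", seed = 3), make_backbone(20, "extended",
# seed = 4), make_sheet() with default geometry. "-" = coil.
ORACLE_DSSP3 <- list(
  helix20_seed3 = "-HHHHHHHHHHHHHHHHHH-",
  extended20_seed4 = "--------------------",
  sheet_default = "-EEEEE---EEEEE--"
)

# minimal classic .dssp text for a chain, built from an 8-class string
write_classic_dssp <- function(resnums, aa, ss8, path, chain = "A") {
  hdr <- c(
    "==== Secondary Structure Definition by the program DSSP (synthetic fixture) ====",
    "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC"
  )
  rows <- vapply(seq_along(resnums), function(k) {
    sprintf("%5d%5d %s %s  %s", k, resnums[k], chain, aa[k],
            ifelse(ss8[k] == "C", " ", ss8[k]))
  }, character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}
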