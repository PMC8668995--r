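# independent oracles and small generators used across the test files

# exhaustive global-alignment oracle: enumerates every alignment of a and b
# (as move sequences) and scores it with affine gaps (open + k * extend per
# gap of length k).  Exponential; only for short strings.
brute_force_align_score <- function(a, b, scheme) {
  ach <- strsplit(a, "")[[1]]
  bch <- strsplit(b, "")[[1]]
  S <- scheme$matrix
  open <- scheme$gap_open
  ext <- scheme$gap_extend
  # state: position in a, position in b, last move (0 none, 1 diag, 2 up, 3 left)
  rec <- function(i, j, last) {
    if (i > length(ach) && j > length(bch)) return(0)
    best <- -Inf
    if (i <= length(ach) && j <= length(bch)) {
      best <- max(best, S[ach[i], bch[j]] + rec(i + 1, j + 1, 1L))
    }
    if (i <= length(ach)) {
      cost <- if (last == 2L) ext else open + ext
      best <- max(best, -cost + rec(i + 1, j, 2L))
    }
    if (j <= length(bch)) {
      cost <- if (last == 3L) ext else open + ext
      best <- max(best, -cost + rec(i, j + 1, 3L))
    }
    best
  }
  rec(1L, 1L, 0L)
}

# naive sliding-window consensus scanner
naive_scan <- function(s, pattern, relaxed = FALSE) {
  hydro <- c("A", "I", "L", "M", "F", "V", "W")
  sch <- strsplit(s, "")[[1]]
  pch <- strsplit(pattern, "")[[1]]
  hits <- integer(0)
  if (length(sch) >= length(pch)) {
    for (i in 1:(length(sch) - length(pch) + 1)) {
      win <- sch[i:(i + length(pch) - 1)]
      ok <- all(mapply(function(p, c) {
        p == "x" || p == c || (relaxed && p %in% hydro && c %in% hydro)
      }, pch, win))
      if (ok) hits <- c(hits, i)
    }
  }
  hits
}

# random protein sequence
random_seq <- function(n, alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]) {
  paste0(sample(alphabet, n, replace = TRUE), collapse = "")
}

random_records <- function(k, len_range = c(5, 40)) {
  lapply(seq_len(k), function(i) {
    seq_record(sprintf("r%03d", i), random_seq(sample(len_range[1]:len_range[2], 1)),
               species = sprintf("species %d", i))
  })
}

# random rotation matrix (uniform via QR)
random_rotation <- function() {
  R <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# angle (degrees) between two rotations
rotation_angle_deg <- function(R1, R2) {
  tr <- sum(diag(t(R1) %*% R2))
  acos(pmin(pmax((tr - 1) / 2, -1), 1)) * 180 / pi
}

expect_same_topology <- function(t1, t2) {
  expect_equal(robinson_foulds(t1, t2), 0)
}
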