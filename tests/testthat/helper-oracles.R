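# Independent oracles used across the suite. Each deliberately takes a
# different computational route than the implementation it checks.

# Exact two-sided Wilcoxon rank-sum p-value by full enumeration of all
# choose(n1 + n2, n1) labelings (no-ties case; mid-ranks handle ties).
enumerate_wilcoxon_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x); N <- length(pooled)
  r <- rank(pooled)
  W_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * (N - n1) / 2
  combs <- utils::combn(N, n1)
  Ws <- apply(combs, 2L, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mean(abs(Ws - mu) >= abs(W_obs - mu) - 1e-9)
}

# Rank two-way ANOVA sums of squares via aov() (sequential SS; equals the
# type-II decomposition for balanced designs), H referred to MS_total.
srh_oracle_balanced <- function(y, A, B) {
  r <- rank(y)
  tab <- summary(stats::aov(r ~ A * B))[[1L]]
  ss <- tab[["Sum Sq"]]
  ss_total <- sum((r - mean(r))^2)
  H <- ss[1:3] / (ss_total / (length(r) - 1))
  list(ss = ss[1:3], H = H,
       p = stats::pchisq(H, tab[["Df"]][1:3], lower.tail = FALSE))
}

# Tetrahedron surface/volume by an independent route: Cayley-Menger
# determinant for the volume, Heron's formula for the four faces.
sa_vol_tetra_oracle <- function(V) {
  d2 <- as.matrix(stats::dist(V))^2
  cm <- rbind(c(0, 1, 1, 1, 1),
              cbind(1, d2))
  vol <- sqrt(det(cm) / 288)
  heron <- function(a, b, c) {
    s <- (a + b + c) / 2
    sqrt(s * (s - a) * (s - b) * (s - c))
  }
  d <- sqrt(d2)
  faces <- utils::combn(4L, 3L)
  sa <- sum(apply(faces, 2L, function(f) {
    heron(d[f[1], f[2]], d[f[1], f[3]], d[f[2], f[3]])
  }))
  sa / vol
}

# Small hand-built straight-leaf track (markers at given y positions).
manual_straight_track <- function(y_by_marker_by_frame, time_s = NULL) {
  frames <- seq_len(nrow(y_by_marker_by_frame))
  markers <- colnames(y_by_marker_by_frame)
  if (is.null(time_s)) time_s <- (frames - 1) * 6
  do.call(rbind, lapply(frames, function(f) {
    data.frame(frame = f, time_s = time_s[f], marker = markers,
               x_mm = 0, y_mm = unname(y_by_marker_by_frame[f, ]))
  }))
}
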