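# Shared low-level helpers: reflect padding and neighborhood offsets.

# Symmetric (edge-repeating) reflection indices for a length-n axis padded
# by r on each side.
reflect_index <- function(n, r) {
  idx <- seq.int(1L - r, n + r)
  idx <- ifelse(idx < 1L, 1L - idx + 0L, idx)      # 0 -> 1, -1 -> 2, ...
  idx <- ifelse(idx > n, 2L * n + 1L - idx, idx)   # n+1 -> n, n+2 -> n-1, ...
  pmin(pmax(idx, 1L), n)
}

pad_reflect <- function(m, r) {
  if (r == 0L) return(m)
  m[reflect_index(nrow(m), r), reflect_index(ncol(m), r), drop = FALSE]
}

# Neighborhood offsets in fixed row-major scan order of the 3x3 window.
neighbor_offsets <- function(connectivity = c("moore8", "neumann4")) {
  connectivity <- match.arg(connectivity)
  if (connectivity == "moore8")
    list(c(-1L, -1L), c(-1L, 0L), c(-1L, 1L), c(0L, -1L),
         c(0L, 1L), c(1L, -1L), c(1L, 0L), c(1L, 1L))
  else
    list(c(-1L, 0L), c(0L, -1L), c(0L, 1L), c(1L, 0L))
}
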