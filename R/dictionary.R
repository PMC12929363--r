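# Square fiducial family used for projected markers ("msq6"): an 8x8 cell
# grid whose outer ring is bright and whose inner 6x6 cells carry a 12-bit
# symbol id plus a 24-bit checksum. Projected markers are high-contrast
# (bright pattern on a dark floor), so decoding needs no error correction:
# the checksum rejects corrupted reads and resolves the 4-fold rotation
# ambiguity (a rotated payload fails the checksum with overwhelming
# probability).

MSQ6_CELLS <- 8L       # total grid including the 1-cell border ring
MSQ6_PAYLOAD <- 6L     # inner payload grid
MSQ6_MAX_ID <- 4095L

int_to_bits <- function(x, n) as.integer(intToBits(x))[1:n]

msq6_checksum <- function(id) {
  c1 <- (id * 997 + 12345) %% 4096
  c2 <- (id * 2731 + 77) %% 4096
  c(int_to_bits(c1, 12), int_to_bits(c2, 12))
}

#' Bit matrix of a square fiducial symbol
#'
#' Returns the 8x8 cell intensities (0 = dark, 1 = bright) of symbol `id`
#' in the package's square fiducial family: bright border ring, 6x6 payload
#' with a 12-bit id and a 24-bit checksum.
#'
#' @param id integer symbol id in `0:4095`.
#' @return 8x8 0/1 integer matrix (row = grid y, column = grid x).
#' @export
marker_bits <- function(id) {
  id <- as.integer(id)
  if (is.na(id) || id < 0 || id > MSQ6_MAX_ID) stop("symbol id out of range 0..4095")
  payload <- c(int_to_bits(id, 12), msq6_checksum(id))
  M <- matrix(1L, MSQ6_CELLS, MSQ6_CELLS)
  M[2:7, 2:7] <- matrix(payload, MSQ6_PAYLOAD, MSQ6_PAYLOAD, byrow = TRUE)
  M
}

# Decode a 6x6 payload matrix (already thresholded to 0/1) trying the four
# rotations. Returns list(id, rot) or NULL.
msq6_decode_payload <- function(P) {
  for (rot in 0:3) {
    bits <- as.integer(t(P))          # row-major
    id <- sum(bits[1:12] * 2^(0:11))
    if (all(bits[13:36] == msq6_checksum(id))) return(list(id = id, rot = rot))
    P <- rot90cw(P)
  }
  NULL
}

# rotate a matrix 90 degrees clockwise
rot90cw <- function(M) t(M[nrow(M):1, , drop = FALSE])
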