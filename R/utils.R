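## Shared constants and small geometry helpers.

#' Standard amino-acid alphabet
#'
#' The 20 standard one-letter amino-acid codes in the fixed column order
#' used by every 9 x 20 matrix in the package.
#'
#' @return Character vector of length 20.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

## 3-letter -> 1-letter residue code (standard residues only)
AA3TO1 <- c(
  ALA = "A", CYS = "C", ASP = "D", GLU = "E", PHE = "F", GLY = "G",
  HIS = "H", ILE = "I", LYS = "K", LEU = "L", MET = "M", ASN = "N",
  PRO = "P", GLN = "Q", ARG = "R", SER = "S", THR = "T", VAL = "V",
  TRP = "W", TYR = "Y"
)
AA1TO3 <- setNames(names(AA3TO1), unname(AA3TO1))

aa_one <- function(resid3) {
  out <- AA3TO1[toupper(resid3)]
  if (anyNA(out)) {
    bad <- unique(toupper(resid3)[is.na(out)])
    stop("nonstandard residue name(s): ", paste(bad, collapse = ", "))
  }
  unname(out)
}

check_sequence <- function(seq) {
  letters1 <- strsplit(seq, "")[[1]]
  bad <- setdiff(letters1, aa_alphabet())
  if (length(bad) > 0) {
    stop("sequence contains nonstandard letter(s): ", paste(bad, collapse = ", "))
  }
  letters1
}

vnorm <- function(v) sqrt(sum(v^2))

unit_vec <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("degenerate zero-length vector")
  v / n
}

## angle at vertex b of a-b-c, in degrees
vec_angle <- function(a, b, c) {
  u <- unit_vec(a - b)
  w <- unit_vec(c - b)
  d <- sum(u * w)
  d <- max(-1, min(1, d))
  acos(d) * 180 / pi
}

## signed torsion of p1-p2-p3-p4 in degrees, range [-180, 180)
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / vnorm(b2)
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ## IUPAC sign convention (matches bio3d::torsion.xyz)
  ang <- atan2(-y, x) * 180 / pi
  wrap_angle(ang)
}

## wrap any angle into [-180, 180)
wrap_angle <- function(a) {
  a <- ((a + 180) %% 360) - 180
  a[a >= 180] <- -180
  a
}

## rotate 3-vectors (rows of m) about unit axis by angle degrees (Rodrigues)
rotate_about_axis <- function(m, axis, angle_deg) {
  k <- unit_vec(axis)
  th <- angle_deg * pi / 180
  one <- if (is.matrix(m)) m else matrix(m, nrow = 1)
  cr <- cbind(k[2] * one[, 3] - k[3] * one[, 2],
              k[3] * one[, 1] - k[1] * one[, 3],
              k[1] * one[, 2] - k[2] * one[, 1])
  kd <- as.vector(one %*% k)
  out <- one * cos(th) + cr * sin(th) + outer(kd, k) * (1 - cos(th))
  if (is.matrix(m)) out else out[1, ]
}

## population standard deviation (divisor n)
pop_sd <- function(x) {
  sqrt(mean((x - mean(x))^2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
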