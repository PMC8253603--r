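## Side-chain dihedral monitoring (chi1/chi2) and Kullback-Leibler
## comparison of angle distributions between two ensembles.

## Per-residue atom defining chi1 (N-CA-CB-X) and chi2 (CA-CB-X-Y).
CHI1_ATOM <- c(
  ARG = "CG", ASN = "CG", ASP = "CG", CYS = "SG", GLN = "CG", GLU = "CG",
  HIS = "CG", ILE = "CG1", LEU = "CG", LYS = "CG", MET = "CG", PHE = "CG",
  PRO = "CG", SER = "OG", THR = "OG1", TRP = "CG", TYR = "CG", VAL = "CG1"
)
CHI2_ATOM <- c(
  ARG = "CD", ASN = "OD1", ASP = "OD1", GLN = "CD", GLU = "CD", HIS = "ND1",
  ILE = "CD1", LEU = "CD1", LYS = "CD", MET = "SD", PHE = "CD1", PRO = "CD",
  TRP = "CD1", TYR = "CD1"
)

#' Side-chain chi1/chi2 dihedrals of one residue in one frame
#'
#' chi1 is the N-CA-CB-G torsion and chi2 the CA-CB-G-D torsion, using the
#' standard per-residue atom tables (e.g. CG1 for Val/Ile chi1, OG1 for
#' Thr). Residues without the relevant side-chain atoms return `NA`
#' (Gly and Ala have no chi1; Ser, Cys, Thr and Val no chi2). Angles are in
#' degrees in `[-180, 180)`.
#'
#' @param ensemble An `EnsembleComplex`.
#' @param chain chain identifier.
#' @param resno author residue number.
#' @param frame 0-based frame identifier.
#' @return Named numeric vector `c(chi1 = , chi2 = )`, possibly `NA`.
#' @export
chi_dihedrals <- function(ensemble, chain, resno, frame = 0) {
  at <- ensemble$atoms
  co <- frame_coords(ensemble, frame)
  rr <- which(at$chain == chain & at$resno == resno)
  if (length(rr) == 0) stop("no residue ", resno, " in chain ", chain)
  resid <- toupper(at$resid[rr][1])
  if (!resid %in% names(AA3TO1)) stop("unsupported residue name: ", resid)
  pos <- function(name) {
    i <- rr[at$elety[rr] == name]
    if (length(i) == 0) NULL else co[i[1], ]
  }
  out <- c(chi1 = NA_real_, chi2 = NA_real_)
  g_name <- CHI1_ATOM[resid]
  if (!is.na(g_name)) {
    p <- list(pos("N"), pos("CA"), pos("CB"), pos(g_name))
    if (!any(vapply(p, is.null, logical(1)))) {
      out["chi1"] <- dihedral_angle(p[[1]], p[[2]], p[[3]], p[[4]])
      d_name <- CHI2_ATOM[resid]
      if (!is.na(d_name)) {
        q <- pos(d_name)
        if (!is.null(q)) {
          out["chi2"] <- dihedral_angle(p[[2]], p[[3]], p[[4]], q)
        }
      }
    }
  }
  out
}

#' Collect a dihedral-angle distribution over an ensemble
#'
#' @param ensemble An `EnsembleComplex`.
#' @param chain chain identifier.
#' @param resno author residue number.
#' @param angle `"chi1"` or `"chi2"`.
#' @param breaks histogram bin edges partitioning `[-180, 180)`; default 36
#'   bins of 10 degrees.
#' @return A `DihedralDistribution` object (see [dihedral_distribution()]).
#' @export
chi_distribution <- function(ensemble, chain, resno, angle = c("chi1", "chi2"),
                             breaks = seq(-180, 180, by = 10)) {
  angle <- match.arg(angle)
  samples <- vapply(seq_len(n_frames(ensemble)) - 1L,
                    function(f) chi_dihedrals(ensemble, chain, resno, f)[[angle]],
                    numeric(1))
  samples <- samples[!is.na(samples)]
  dihedral_distribution(samples, angle, breaks)
}

#' Construct a dihedral-angle distribution
#'
#' @param samples angles in degrees in `[-180, 180)` (values outside are
#'   wrapped).
#' @param angle_name `"chi1"` or `"chi2"`.
#' @param breaks monotone bin edges partitioning `[-180, 180)`.
#' @return Object of class `DihedralDistribution` with elements `samples`,
#'   `angle_name`, `breaks`.
#' @export
dihedral_distribution <- function(samples, angle_name = "chi1",
                                  breaks = seq(-180, 180, by = 10)) {
  if (length(samples) < 1) stop("distribution needs at least one sample")
  if (is.unsorted(breaks, strictly = TRUE) ||
      abs(breaks[1] + 180) > 1e-9 || abs(breaks[length(breaks)] - 180) > 1e-9) {
    stop("breaks must be a strictly increasing partition of [-180, 180)")
  }
  structure(list(samples = wrap_angle(samples), angle_name = angle_name,
                 breaks = breaks),
            class = "DihedralDistribution")
}

hist_counts <- function(d) {
  ## right-open bins [a, b); the wrap convention keeps samples < 180
  cut_idx <- findInterval(d$samples, d$breaks, rightmost.closed = FALSE,
                          left.open = FALSE)
  tabulate(cut_idx, nbins = length(d$breaks) - 1)
}

#' Kullback-Leibler divergence between dihedral distributions
#'
#' Histograms both distributions on their (identical) bins, adds a
#' pseudocount of `1/(n_samples * n_bins)` to every bin of each histogram,
#' normalizes, and returns `D_KL(P || Q) = sum_b P(b) log(P(b)/Q(b))`
#' (natural log). Zero iff the regularized histograms are identical; not
#' symmetric in its arguments.
#'
#' @param p,q `DihedralDistribution` objects with identical `breaks`.
#' @return Non-negative scalar.
#' @seealso [kl_from_probs()] for the bare closed form on probability
#'   vectors.
#' @export
kl_divergence <- function(p, q) {
  stopifnot(inherits(p, "DihedralDistribution"),
            inherits(q, "DihedralDistribution"))
  if (length(p$breaks) != length(q$breaks) ||
      any(abs(p$breaks - q$breaks) > 1e-9)) {
    stop("mismatched histogram binning")
  }
  nb <- length(p$breaks) - 1
  cp <- hist_counts(p) + 1 / (length(p$samples) * nb)
  cq <- hist_counts(q) + 1 / (length(q$samples) * nb)
  kl_from_probs(cp / sum(cp), cq / sum(cq))
}

#' Kullback-Leibler divergence of two probability vectors
#'
#' `sum(p * log(p / q))` with natural log; `p` entries equal to zero
#' contribute zero. Both vectors must be strictly positive where `p > 0`
#' and sum to one.
#'
#' @param p,q probability vectors of equal length.
#' @return Non-negative scalar.
#' @export
kl_from_probs <- function(p, q) {
  if (length(p) != length(q)) stop("probability vectors differ in length")
  if (abs(sum(p) - 1) > 1e-6 || abs(sum(q) - 1) > 1e-6) {
    stop("inputs must sum to 1")
  }
  nz <- p > 0
  if (any(q[nz] <= 0)) stop("q has zero mass where p is positive")
  sum(p[nz] * log(p[nz] / q[nz]))
}
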