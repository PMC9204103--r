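# Peptide-bond geometry. The omega dihedral (CA_i, C_i, N_{i+1}, CA_{i+1})
# distinguishes the trans conformer (omega ~ 180 deg) from the cis conformer
# (omega ~ 0 deg) of an X-Pro bond; isomerization flips the bond by roughly
# 180 degrees.

#' Signed omega dihedral from four backbone atoms
#'
#' @param ca_i,c_i,n_next,ca_next Numeric xyz coordinates (Angstrom) of
#'   CA(i), C(i), N(i+1), CA(i+1).
#' @return Signed dihedral in degrees, in (-180, 180].
#' @export
omega_angle <- function(ca_i, c_i, n_next, ca_next) {
  pts <- rbind(ca_i, c_i, n_next, ca_next)
  if (nrow(unique(pts)) < 4L) stop("the four atoms must be distinct")
  b0 <- ca_i - c_i
  b1 <- n_next - c_i
  b2 <- ca_next - n_next
  b1 <- b1 / sqrt(sum(b1^2))
  # components of the flanking bonds perpendicular to the central bond
  v <- b0 - sum(b0 * b1) * b1
  w <- b2 - sum(b2 * b1) * b1
  if (sqrt(sum(v^2)) < 1e-9 || sqrt(sum(w^2)) < 1e-9)
    stop("degenerate geometry: three collinear atoms")
  ang <- atan2(sum(.cross3(b1, v) * w), sum(v * w)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Classify a peptide bond as cis, trans, or twisted
#'
#' cis if |omega| <= \code{cis_halfwidth_deg}; trans if |180 - |omega|| <=
#' \code{trans_halfwidth_deg}; otherwise twisted.
#'
#' @param omega_deg Dihedral in degrees, in (-180, 180].
#' @param cis_halfwidth_deg,trans_halfwidth_deg Classification half-widths
#'   (default 30 degrees each).
#' @return "cis", "trans", or "twisted" (vectorized).
#' @export
classify_isomer <- function(omega_deg, cis_halfwidth_deg = 30,
                            trans_halfwidth_deg = 30) {
  if (any(omega_deg <= -180 | omega_deg > 180))
    stop("omega must lie in (-180, 180]")
  out <- rep("twisted", length(omega_deg))
  out[abs(omega_deg) <= cis_halfwidth_deg] <- "cis"
  out[abs(180 - abs(omega_deg)) <= trans_halfwidth_deg] <- "trans"
  out
}

#' Per-residue omega angles from a PDB file
#'
#' Reads backbone ATOM records (via bio3d) and reports, for every
#' consecutive residue pair of each chain, the omega dihedral and its
#' cis/trans classification.
#'
#' @param path PDB file.
#' @param chain Optional chain id to restrict to.
#' @param cis_halfwidth_deg,trans_halfwidth_deg Passed to
#'   \code{\link{classify_isomer}}.
#' @return data.frame(chain, resno_i, resno_next, omega_deg, class).
#' @export
omega_from_pdb <- function(path, chain = NULL, cis_halfwidth_deg = 30,
                           trans_halfwidth_deg = 30) {
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom[pdb$atom$elety %in% c("CA", "C", "N"), , drop = FALSE]
  if (!is.null(chain)) at <- at[at$chain %in% chain, , drop = FALSE]
  rows <- list()
  for (ch in unique(at$chain)) {
    a <- at[at$chain == ch, , drop = FALSE]
    resnos <- sort(unique(a$resno))
    get <- function(rn, ty) {
      hit <- a[a$resno == rn & a$elety == ty, c("x", "y", "z")]
      if (nrow(hit) == 0L) NULL else as.numeric(hit[1, ])
    }
    for (k in seq_len(length(resnos) - 1L)) {
      ri <- resnos[k]; rn <- resnos[k + 1L]
      if (rn != ri + 1L) next
      ca1 <- get(ri, "CA"); c1 <- get(ri, "C")
      n2 <- get(rn, "N"); ca2 <- get(rn, "CA")
      if (is.null(ca1) || is.null(c1) || is.null(n2) || is.null(ca2)) next
      om <- omega_angle(ca1, c1, n2, ca2)
      rows[[length(rows) + 1L]] <- data.frame(
        chain = ch, resno_i = ri, resno_next = rn, omega_deg = om,
        class = classify_isomer(om, cis_halfwidth_deg, trans_halfwidth_deg),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(chain = character(0), resno_i = integer(0),
                      resno_next = integer(0), omega_deg = numeric(0),
                      class = character(0), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
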