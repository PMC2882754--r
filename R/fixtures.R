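# Reference sequences used throughout the package: the designer reporter
# tails, the vector tail peptide, and the library-derived tails.
#
# The four designer variable regions are built by the published construction
# rule: eight amino acids between common proline and valine residues, either
# all alanine or with two to four alanines replaced so that each classical
# motif class is represented (YAAL for YXXphi, EAAALL for the acidic
# dileucine, FANPAY for FXNPXY).
#
# The five library tails (CD8-PIA, -PNT, -WPK, -RYR, -STS; named after the
# first three insert residues) were published only as a figure image, so the
# full sequences here are synthetic reconstructions: every residue fixed by
# the mutagenesis record is honoured (see below), alanine fills the
# unconstrained positions, and the vector context KRLKRRRI...IPISTFHDDR
# frames the in-frame inserts. They reproduce the published scan outcome —
# exactly one of the five (STS, via YQSI) carries a classical
# internalization motif — but are not the original inserts.

#' Fixture sequences: designer tails, vector tail, library-derived tails
#'
#' @return a list with components:
#' \describe{
#'   \item{designer_tails}{named character vector (`8xA`, `YAAL`, `EAAALL`,
#'     `FANPAY`) of designer tail regions, each `P` + 8 residues + `V`.}
#'   \item{vector_tail}{the empty reporter vector's cytoplasmic tail peptide,
#'     `KRLKRRRIPISTFHDDR`.}
#'   \item{ryr_insert_prefix}{first nine insert residues of CD8-RYR,
#'     `RYRRSLNHK` (numbering fixes Y2, L6, N7 as the key residues).}
#'   \item{ctla4_cterm}{the C-terminal octapeptide of CTLA-4, `QPYFIPIN`,
#'     carrying YXXXphiN as `YFIPIN`.}
#'   \item{library_inserts}{named character vector of the five library insert
#'     peptides (synthetic reconstructions, see Details).}
#'   \item{library_tails}{the corresponding full tail peptides in vector
#'     context.}
#'   \item{reconstructed}{named logical over `library_tails`: `TRUE` for all
#'     five, flagging that they are reconstructions, not published
#'     sequences.}
#' }
#'
#' @details Residues fixed by the mutagenesis record and honoured in the
#' reconstructions: PIA — insert starts `PIA`, `DQD` at 5-7, `ILS` at 8-10,
#' `PIL` at 11-13 (two IL dileucine-like pairs with acidic residues at -1/-3
#' of the first and -5/-7 of the second); PNT — starts `PNT`, `RHN` at 4-6,
#' `TPL` at 10-12, in-frame so the vector `IPI`/`DDR` residues follow; WPK —
#' starts `WPK`, `LES` at 4-6, `QLD` at 7-9, C-terminal `WF`, out of frame
#' (no vector C-terminus); RYR — starts `RYRRSLNHK` (YXXXphiN as `YRRSLN`);
#' STS — starts `STS` and contains the classical YXXphi `YQSI`. Unconstrained
#' positions are alanine.
#'
#' @examples
#' fixtures()$ctla4_cterm
#' @export
fixtures <- function() {
  designer_vars <- c(
    `8xA`    = "AAAAAAAA",
    YAAL     = "AAYAALAA",
    EAAALL   = "AEAAALLA",
    FANPAY   = "AFANPAYA")
  designer_tails <- vapply(designer_vars, function(v) paste0("P", v, "V"), "")
  inserts <- c(
    PIA = "PIAADQDILSPIL",
    PNT = "PNTRHNAAATPL",
    WPK = "WPKLESQLDAAWF",
    RYR = "RYRRSLNHK",
    STS = "STSYQSIAA")
  in_frame <- c(PIA = TRUE, PNT = TRUE, WPK = FALSE, RYR = TRUE, STS = TRUE)
  library_tails <- vapply(names(inserts), function(nm) {
    if (in_frame[[nm]]) {
      paste0("KRLKRRRI", inserts[[nm]], "IPISTFHDDR")
    } else {
      paste0("KRLKRRRI", inserts[[nm]])
    }
  }, "")
  list(designer_tails = designer_tails,
       vector_tail = "KRLKRRRIPISTFHDDR",
       ryr_insert_prefix = "RYRRSLNHK",
       ctla4_cterm = "QPYFIPIN",
       library_inserts = inserts,
       library_tails = library_tails,
       reconstructed = stats::setNames(rep(TRUE, length(library_tails)),
                                       names(library_tails)))
}
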