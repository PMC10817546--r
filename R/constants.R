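#' Primer set used for the ITS1 and ITS2 amplicon pools
#'
#' The four universal fungal primers amplifying the two internal transcribed
#' spacers of the rRNA cistron: ITS5/ITS-2RK for ITS1 and ITS3/ITS4 for ITS2.
#' Forward primers appear verbatim at the 5' end of an amplicon; the reverse
#' complement of the reverse primer closes its 3' end.
#'
#' @return Named list with elements `ITS1` and `ITS2`, each a list with
#'   `fwd` and `rev` primer strings (5'->3').
#' @export
amf_primers <- function() {
  list(
    ITS1 = list(fwd = "GGAAGTAAAAGTCGTAACAAGG", rev = "CGTTCAAAGATTCGATGATTCAC"),
    ITS2 = list(fwd = "GCATCGATGAAGAACGCAGC",   rev = "TCCTCCGCTTATTGATATGC")
  )
}

# Synthetic conserved rRNA coding segments flanking the spacers in the
# simulated 18S-ITS1-5.8S-ITS2-28S construct. Fixed (seed-independent) so that
# anchor-based spacer trimming has stable motifs to search for. These are
# invented stand-ins, not real rRNA sequence.
SSU_TAIL <- "CGCATAGCGAGATAGGATATCTTCTGCAGCTTAAGCCTGA"
R58S     <- "AGTTGTATTGGCACCAGCTTTAGGCTACCTACCTCTTATGTTATAGTACA"
LSU_HEAD <- "TCTAAACATACGCTCTTTTTGGCCACGCGCCGTCTCCTAT"

# Number of conserved bases carried into an amplicon on each side of a spacer;
# these flanks are what trim_rrna removes after OTU construction.
ANCHOR_LEN <- 15L

#' Conserved anchor motifs used for spacer trimming
#'
#' The short conserved rRNA segments that the simulator places immediately
#' up- and downstream of each spacer inside an amplicon, and that
#' [trim_rrna()] locates (allowing one mismatch) to cut out the spacer.
#'
#' @return Named list with `ITS1` and `ITS2` entries, each holding `left`
#'   and `right` anchor strings.
#' @export
amf_anchors <- function() {
  list(
    ITS1 = list(left  = substr(SSU_TAIL, nchar(SSU_TAIL) - ANCHOR_LEN + 1L, nchar(SSU_TAIL)),
                right = substr(R58S, 1L, ANCHOR_LEN)),
    ITS2 = list(left  = substr(R58S, nchar(R58S) - ANCHOR_LEN + 1L, nchar(R58S)),
                right = substr(LSU_HEAD, 1L, ANCHOR_LEN))
  )
}
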