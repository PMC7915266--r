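# Bundled IMGT-style catalogue of functional human TRA/TRB gene segments.
# The TRBV list is pinned at 30 entries so that "k-of-30" deployment
# percentages have a stable, documented denominator; the catalogue is a
# package choice, not a complete IMGT export.
.tcr_catalogue <- list(
  TRBV = c("TRBV2", "TRBV3-1", "TRBV4-1", "TRBV4-2", "TRBV5-1", "TRBV5-4",
           "TRBV5-5", "TRBV5-6", "TRBV6-1", "TRBV6-4", "TRBV6-5", "TRBV7-2",
           "TRBV7-3", "TRBV7-6", "TRBV7-8", "TRBV7-9", "TRBV9", "TRBV10-3",
           "TRBV11-2", "TRBV12-3", "TRBV13", "TRBV14", "TRBV15", "TRBV18",
           "TRBV19", "TRBV20-1", "TRBV24-1", "TRBV27", "TRBV28", "TRBV30"),
  TRBJ = c("TRBJ1-1", "TRBJ1-2", "TRBJ1-3", "TRBJ1-4", "TRBJ1-5", "TRBJ1-6",
           "TRBJ2-1", "TRBJ2-2", "TRBJ2-3", "TRBJ2-4", "TRBJ2-5", "TRBJ2-6",
           "TRBJ2-7"),
  TRBD = c("TRBD1", "TRBD2"),
  TRAV = c("TRAV1-2", "TRAV2", "TRAV3", "TRAV4", "TRAV5", "TRAV8-1",
           "TRAV8-2", "TRAV8-4", "TRAV9-2", "TRAV12-1", "TRAV12-2",
           "TRAV13-1", "TRAV14", "TRAV16", "TRAV17", "TRAV19", "TRAV21",
           "TRAV22", "TRAV24", "TRAV25", "TRAV26-1", "TRAV27", "TRAV29",
           "TRAV35", "TRAV38-1", "TRAV41"),
  TRAJ = c("TRAJ6", "TRAJ9", "TRAJ10", "TRAJ12", "TRAJ13", "TRAJ15",
           "TRAJ20", "TRAJ22", "TRAJ23", "TRAJ24", "TRAJ27", "TRAJ28",
           "TRAJ30", "TRAJ31", "TRAJ33", "TRAJ34", "TRAJ36", "TRAJ37",
           "TRAJ39", "TRAJ40", "TRAJ42", "TRAJ43", "TRAJ44", "TRAJ45",
           "TRAJ47", "TRAJ48", "TRAJ49", "TRAJ52", "TRAJ53", "TRAJ54")
)

#' Bundled gene-segment catalogue
#'
#' Returns the package's reference list of functional gene-segment names for
#' one segment kind. The TRBV catalogue contains exactly 30 genes so that
#' deployment statistics ("k of 30 genes used") have a fixed denominator.
#'
#' @param segment_kind One of `"TRBV"`, `"TRBJ"`, `"TRBD"`, `"TRAV"`,
#'   `"TRAJ"`.
#' @return Character vector of canonical allele-free gene labels.
#' @examples
#' length(gene_catalogue("TRBV")) # 30
#' @export
gene_catalogue <- function(segment_kind = c("TRBV", "TRBJ", "TRBD",
                                            "TRAV", "TRAJ")) {
  segment_kind <- match.arg(segment_kind)
  .tcr_catalogue[[segment_kind]]
}
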