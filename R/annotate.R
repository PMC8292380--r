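# Interval-based genomic-context annotation of CpG sites: CpG-density
# classes (island > shore > open sea) and genic classes (promoter > exon >
# intron > intergenic), plus a label-fraction enrichment table comparing
# DMSs with all tested sites.

.track_granges <- function(track) {
  .assert(all(c("chrom", "start", "end", "label") %in% names(track)),
          "track needs chrom, start, end, label (0-based half-open)")
  .assert(all(track$end > track$start),
          "malformed intervals: end must be > start")
  GenomicRanges::GRanges(
    seqnames = track$chrom,
    ranges = IRanges::IRanges(start = track$start + 1L, end = track$end),
    label = track$label)
}

#' Read an annotation track from a BED file
#'
#' Standard BED (0-based half-open); the `name` field supplies the interval
#' label (e.g. `island`, `shore`, `promoter`, `exon`, `intron`).
#'
#' @param path BED file path.
#' @return data frame with `chrom`, `start`, `end`, `label`.
#' @export
read_annotation_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             label = if (!is.null(gr$name)) as.character(gr$name)
                     else NA_character_,
             stringsAsFactors = FALSE)
}

.label_sites <- function(sites_gr, track, precedence, fallback) {
  lab <- rep(fallback, length(sites_gr))
  if (is.null(track) || nrow(track) == 0L) return(lab)
  gr <- .track_granges(track)
  for (lv in rev(precedence)) {       # apply lowest precedence first
    sel <- gr[gr$label == lv]
    if (length(sel) == 0L) next
    hit <- IRanges::overlapsAny(sites_gr, sel)
    lab[hit] <- lv
  }
  lab
}

#' Annotate CpG sites with genomic-context labels
#'
#' Each site gets one CpG-density label with precedence island > shore >
#' open sea, and one genic label with precedence promoter > exon > intron >
#' intergenic (a site inside both an island and a shore interval is an
#' island).  When `is_dms` flags are supplied, a label-fraction enrichment
#' table comparing DMSs against all tested sites is attached as attribute
#' `"enrichment"`.
#'
#' @param sites data frame with `chrom`, `pos` (0-based) and optionally
#'   `site_id` and `is_dms`.
#' @param cpg_track,genic_track interval data frames (`chrom`, `start`,
#'   `end`, `label`; 0-based half-open), e.g. from [read_annotation_bed()].
#' @return data frame `site_id`, `chrom`, `pos`, `cpg_context`,
#'   `genic_context` (plus `is_dms` when supplied).
#' @export
annotate_sites <- function(sites, cpg_track = NULL, genic_track = NULL) {
  .assert(all(c("chrom", "pos") %in% names(sites)), "sites needs chrom, pos")
  sgr <- GenomicRanges::GRanges(
    seqnames = sites$chrom,
    ranges = IRanges::IRanges(start = sites$pos + 1L, width = 1L))
  out <- data.frame(
    site_id = sites$site_id %||% paste0(sites$chrom, ":", sites$pos),
    chrom = sites$chrom, pos = sites$pos,
    cpg_context = .label_sites(sgr, cpg_track,
                               c("island", "shore"), "open_sea"),
    genic_context = .label_sites(sgr, genic_track,
                                 c("promoter", "exon", "intron"),
                                 "intergenic"),
    stringsAsFactors = FALSE)
  if (!is.null(sites$is_dms)) {
    out$is_dms <- sites$is_dms
    enr <- do.call(rbind, lapply(c("cpg_context", "genic_context"),
                                 function(col) {
      labs <- sort(unique(out[[col]]))
      dms <- out$is_dms %in% TRUE
      data.frame(track = col, label = labs,
                 frac_all = as.numeric(table(factor(out[[col]], labs)) /
                                         nrow(out)),
                 frac_dms = if (any(dms))
                   as.numeric(table(factor(out[[col]][dms], labs)) / sum(dms))
                 else NA_real_,
                 stringsAsFactors = FALSE)
    }))
    attr(out, "enrichment") <- enr
  }
  out
}
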