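## Human-readable table export: TSV and XLSX, cell-identical.

#' Write a ranked alignment set as a table
#'
#' One row per segment with accessions, 1-based inclusive display
#' coordinates, orientation, identity, gap/mismatch counts, alignment
#' length and reciprocity. The TSV and XLSX outputs are cell-identical.
#'
#' @param ranked a [RankedAlignmentSet-class].
#' @param path output file.
#' @param format `"tsv"` or `"xlsx"`.
#' @return Invisibly, the path.
#' @export
writeAlignmentTable <- function(ranked, path, format = c("tsv", "xlsx")) {
  if (length(format) != 1L || !format %in% c("tsv", "xlsx"))
    stop("unsupported table format: ", paste(format, collapse = "/"),
         " (use 'tsv' or 'xlsx')")
  df <- as.data.frame(ranked)
  if (format == "tsv") {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    .writeXlsx(df, path, sheet = "Alignments")
  }
  invisible(path)
}

#' Read an alignment table written by [writeAlignmentTable()]
#'
#' Reconstructs a [RankedAlignmentSet-class] from the TSV layout. Block
#' structure is not carried by the table, so each segment comes back as a
#' single diagonal block (flagged low-resolution when the original had
#' internal gaps); all tabulated fields round-trip exactly.
#'
#' @param path a TSV written by [writeAlignmentTable()].
#' @return A [RankedAlignmentSet-class].
#' @export
readAlignmentTable <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  for (col in c("query_assembly", "target_assembly")) {
    df[[col]] <- as.character(df[[col]])
    df[[col]][is.na(df[[col]])] <- ""
  }
  segs <- lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    span <- r$matches + r$mismatches
    lowres <- span < r$query_end - r$query_start + 1 ||
      span < r$target_end - r$target_start + 1
    AlignmentSegment(r$query_seq, r$query_start - 1, r$query_end,
      r$target_seq, r$target_start - 1, r$target_end,
      orientation = r$orientation,
      blocks = cbind(r$query_start - 1,
                     if (r$orientation == "forward") r$target_start - 1
                     else r$target_end - span, span),
      matches = r$matches, mismatches = r$mismatches,
      gapCount = r$gap_count, gapBases = r$gap_bases,
      qassembly = r$query_assembly, tassembly = r$target_assembly,
      lowres = lowres)
  })
  new("RankedAlignmentSet", segments = segs,
      reciprocity = as.integer(df$reciprocity))
}
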