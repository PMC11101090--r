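## FASTA ingest and the optional sequence-role metadata sidecar.

#' Read an assembly from FASTA
#'
#' Sequence names and lengths populate an [AssemblyInfo-class]; roles
#' (chromosome vs unplaced scaffold) come from an optional two-column
#' metadata TSV (`seq_id<TAB>role`, see [readSeqReport()]). When no
#' metadata is given every sequence is treated as a chromosome and a
#' warning is issued, since the ranking prefers chromosome placements.
#'
#' @param path FASTA file.
#' @param assemblyId assembly accession.
#' @param rolesPath optional role TSV.
#' @param name assembly display name.
#' @return List with `info` ([AssemblyInfo-class]) and `sequences`
#'   (a `DNAStringSet`).
#' @export
readAssemblyFasta <- function(path, assemblyId = basename(path),
                              rolesPath = NULL, name = assemblyId) {
  seqs <- Biostrings::readDNAStringSet(path)
  ids <- sub("[ \t].*$", "", names(seqs))
  if (anyDuplicated(ids))
    stop("duplicate sequence ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(seqs) <- ids
  roles <- "chromosome"
  if (!is.null(rolesPath)) {
    rl <- readSeqReport(rolesPath)
    roles <- rl$role[match(ids, rl$seq_id)]
    if (anyNA(roles)) {
      warning("no role metadata for ",
              paste(ids[is.na(roles)], collapse = ", "),
              "; treating as chromosome")
      roles[is.na(roles)] <- "chromosome"
    }
  } else {
    warning("no sequence role metadata: treating every sequence of ",
            assemblyId, " as a chromosome")
  }
  list(info = AssemblyInfo(assemblyId, ids, Biostrings::width(seqs),
                           roles, name = name),
       sequences = seqs)
}

#' Read a sequence role report
#'
#' A headered TSV with columns `seq_id` and `role` (and optionally
#' `length`), assigning each assembly sequence its chromosome /
#' unplaced-scaffold role.
#'
#' @param path TSV file.
#' @return data.frame with columns `seq_id`, `role` (and `length` if
#'   present).
#' @export
readSeqReport <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("seq_id", "role") %in% names(df)))
    stop("sequence report needs columns seq_id and role")
  if (!all(df$role %in% c("chromosome", "unplaced_scaffold")))
    stop("roles must be 'chromosome' or 'unplaced_scaffold'")
  df
}

#' Write a sequence role report
#' @param info an [AssemblyInfo-class].
#' @param path output TSV.
#' @return Invisibly, the path.
#' @export
writeSeqReport <- function(info, path) {
  write.table(info@seqs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
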