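PLATESET_COLS <- c("plate_id", "well_role", "sample_id", "mirna_id",
                   "replicate", "ct", "known_copies")

#' Write / read a plate set as long-format TSV
#'
#' One row per well: `plate_id, well_role (sample|standard|ntc|spike),
#' sample_id, mirna_id, replicate, ct, known_copies` (standards only).
#'
#' @param plates a `plate_set`.
#' @param path file path.
#' @export
write_plateset <- function(plates, path) {
  write.table(as.data.frame(plates)[, PLATESET_COLS], path, sep = "\t",
              quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_plateset
#' @export
read_plateset <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, na.strings = "")
  missing <- setdiff(PLATESET_COLS, names(df))
  if (length(missing))
    stop("plate-set file lacks column(s): ", paste(missing, collapse = ", "))
  roles_ok <- df$well_role %in% c("sample", "standard", "ntc", "spike")
  if (!all(roles_ok))
    stop("malformed well role at line ", which(!roles_ok)[1] + 1L)
  bad_ct <- !is.na(df$ct) & (df$ct < 0 | df$ct > 45)
  if (any(bad_ct))
    stop("Ct outside [0, 45] at line ", which(bad_ct)[1] + 1L)
  df <- df[, PLATESET_COLS]
  class(df) <- c("plate_set", "data.frame")
  df
}

#' Write / read an expression matrix as TSV
#'
#' Samples as rows (first column `sample_id`), miRNAs as columns; values
#' are log2 copies (or any normalized transform thereof). Reading matches
#' columns by header name, so column order is irrelevant.
#'
#' @param m numeric matrix with sample row names.
#' @param path file path.
#' @export
write_matrix <- function(m, path) {
  df <- data.frame(sample_id = rownames(m), as.data.frame(m),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"sample_id" %in% names(df)) stop("matrix file lacks `sample_id` column")
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample id(s): ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  mir <- setdiff(names(df), "sample_id")
  if (anyDuplicated(mir))
    stop("duplicate miRNA column(s): ",
         paste(unique(mir[duplicated(mir)]), collapse = ", "))
  m <- as.matrix(df[, mir, drop = FALSE])
  rownames(m) <- df$sample_id
  m[, sort(mir), drop = FALSE]
}

#' Write / read sample annotation TSV
#' @param annotation data frame with `sample_id, class, tissue_site,
#'   collection_site, cohort`.
#' @param path file path.
#' @export
write_annotation <- function(annotation, path) {
  write.table(annotation, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotation
#' @export
read_annotation <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "class", "tissue_site", "collection_site", "cohort")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("annotation lacks column(s): ", paste(missing, collapse = ", "))
  bad <- !df$class %in% ALL_CLASSES
  if (any(bad)) stop("unknown class at line ", which(bad)[1] + 1L)
  df
}

#' Read / write gene-set collections in GMT format
#'
#' Standard tab-separated layout: set name, description, then member genes.
#'
#' @param path file path.
#' @return named list of unique gene-id vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop("malformed GMT line ", i, ": expected name, description, genes")
    genes <- unique(f[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (!length(genes)) stop("empty gene set at GMT line ", i)
    out[[f[1]]] <- genes
  }
  out
}

#' @rdname read_gmt
#' @param pathways named list of gene-id vectors.
#' @export
write_gmt <- function(pathways, path) {
  lines <- vapply(names(pathways), function(nm)
    paste(c(nm, "na", pathways[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write the miRNA-target interaction table
#'
#' TSV with columns `mirna_id, gene_id` (optional `evidence`); rows must be
#' unique and ids non-empty.
#'
#' @param path file path.
#' @export
read_target_map <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("mirna_id", "gene_id")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("target map lacks column(s): ", paste(missing, collapse = ", "))
  bad <- is.na(df$mirna_id) | is.na(df$gene_id) |
    !nzchar(df$mirna_id) | !nzchar(df$gene_id)
  if (any(bad)) stop("empty id at line ", which(bad)[1] + 1L)
  dup <- duplicated(df[, need])
  if (any(dup)) stop("duplicate interaction at line ", which(dup)[1] + 1L)
  df
}

#' @rdname read_target_map
#' @param target_map the interaction data frame.
#' @export
write_target_map <- function(target_map, path) {
  write.table(target_map, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize / restore a marker panel as JSON
#' @param panel a `marker_panel`.
#' @param path file path.
#' @export
write_panel <- function(panel, path) {
  jsonlite::write_json(list(entries = panel$entries,
                            counts = as.list(panel$counts)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  entries <- as.data.frame(obj$entries, stringsAsFactors = FALSE)
  assemble_panel(
    ovr = entries[entries$tier == "ovr", ],
    ovo = entries[entries$tier == "ovo", ],
    housekeeping = entries$mirna_id[entries$tier == "housekeeping"]
  )
}
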