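# Reading and writing molecule records: SMILES lists, CSV with a smiles
# column, and SDF (V2000).

#' Read molecule records from a file
#'
#' Supported formats (by extension): `.smi`/`.smiles` (one SMILES per line,
#' optional whitespace-separated id), `.csv` (columns `smiles` and optionally
#' `id` plus numeric columns, which are carried through), `.sdf` (V2000; sets
#' the 3D flag when coordinates are present). Invalid entries are collected
#' into the `"failures"` attribute, not silently dropped.
#'
#' @param path input file
#' @return a `molecule_records` data frame
#' @export
read_molecules <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("smi", "smiles", "txt")) {
    lines <- trimws(readLines(path, warn = FALSE))
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0) stop("empty input: ", path)
    parts <- strsplit(lines, "[[:space:]]+")
    smiles <- vapply(parts, `[[`, character(1), 1)
    ids <- vapply(seq_along(parts), function(i) {
      if (length(parts[[i]]) > 1) parts[[i]][2] else paste0("M", i)
    }, character(1))
    molecule_records(smiles, ids)
  } else if (ext == "csv") {
    df <- read.csv(path, stringsAsFactors = FALSE)
    if (!"smiles" %in% names(df)) stop("CSV lacks a 'smiles' column: ", path)
    ids <- if ("id" %in% names(df)) as.character(df$id) else paste0("M", seq_len(nrow(df)))
    recs <- molecule_records(df$smiles, ids)
    extra <- setdiff(names(df), c(names(recs), "id", "smiles"))
    for (col in extra) recs[[col]] <- df[[col]][match(recs$id, ids)]
    recs
  } else if (ext == "sdf") {
    sdfset <- ChemmineR::read.SDFset(path)
    ids <- ChemmineR::sdfid(sdfset)
    ids[is.na(ids) | ids == ""] <- paste0("M", which(is.na(ids) | ids == ""))
    if (anyDuplicated(ids)) ids <- make.unique(ids, sep = "_")
    valid <- ChemmineR::validSDF(sdfset)
    failures <- ids[!valid]
    sdfset <- sdfset[valid]
    ids <- ids[valid]
    if (length(sdfset) == 0) stop("no valid records in ", path)
    smiles <- as.character(ChemmineR::sdf2smiles(sdfset))
    recs <- molecule_records(smiles, ids)
    failures <- c(failures, attr(recs, "failures"))
    graphs <- lapply(seq_along(sdfset), function(i) mol_graph_from_sdf(sdfset[[i]]))
    names(graphs) <- ids
    recs$is_3d <- vapply(recs$id, function(id) !is.null(graphs[[id]]$coords), logical(1))
    attr(recs, "graphs") <- graphs[recs$id]
    attr(recs, "failures") <- failures
    recs
  } else {
    stop("unrecognized format: .", ext, " (expected .smi, .csv or .sdf)")
  }
}

#' Write molecule records to CSV
#'
#' Emits `id`, `smiles` and all numeric columns; a round trip through
#' [read_molecules()] reproduces ids, canonical structures and the numeric
#' columns.
#'
#' @param records a `molecule_records` data frame
#' @param path output file
#' @export
write_molecules <- function(records, path) {
  keep <- c("id", "smiles",
            names(records)[vapply(records, is.numeric, logical(1))])
  write.csv(records[, unique(keep), drop = FALSE], path, row.names = FALSE)
  invisible(path)
}
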