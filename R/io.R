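#' @importFrom utils read.delim write.table head
NULL

parseSampleNames <- function(nms) {
  m <- regmatches(nms, regexec("^P(\\d+)_B(\\d+)_T(\\d+)$", nms))
  bad <- vapply(m, length, integer(1)) != 4L
  if (any(bad))
    stop("sample name(s) not of the form P<pop>_B<biorep>_T<techrep>: ",
         paste(head(nms[bad], 5), collapse = ", "))
  data.frame(population = as.integer(vapply(m, `[`, character(1), 2)),
             biorep = as.integer(vapply(m, `[`, character(1), 3)),
             techrep = as.integer(vapply(m, `[`, character(1), 4)))
}

makeSE <- function(x, designDf) {
  nPop <- max(designDf$population)
  cd <- S4Vectors::DataFrame(
    population = factor(sprintf("P%d", designDf$population),
                        levels = sprintf("P%d", seq_len(nPop))),
    biorep = designDf$biorep, techrep = designDf$techrep,
    row.names = colnames(x))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = x), colData = cd)
}

#' Read a protein-group intensity table
#'
#' Two dialects are supported. `synthetic`: first column the protein id,
#' remaining columns named `P<pop>_B<biorep>_T<techrep>` holding raw
#' intensities. `proteinGroups`: a MaxQuant-style table with a configurable
#' id column and intensity columns named `<intensityPrefix><sample>`, the
#' sample part again encoding the design. Duplicate protein ids are an
#' error (all joins key on them); zeros mean missing.
#'
#' @param path TSV file.
#' @param dialect input dialect.
#' @param idColumn id column for the `proteinGroups` dialect.
#' @param intensityPrefix intensity column prefix for `proteinGroups`.
#' @return a `SummarizedExperiment` with assay `intensity` and the design
#'   in `colData`.
#' @export
readAbundanceTable <- function(path, dialect = c("synthetic",
                                                 "proteinGroups"),
                               idColumn = "Majority protein IDs",
                               intensityPrefix = "Intensity ") {
  dialect <- match.arg(dialect)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (dialect == "synthetic") {
    ids <- as.character(df[[1]])
    mat <- as.matrix(df[, -1, drop = FALSE])
  } else {
    if (!idColumn %in% names(df)) stop("id column not found: ", idColumn)
    ids <- as.character(df[[idColumn]])
    intCols <- grep(paste0("^", intensityPrefix), names(df), value = TRUE)
    if (!length(intCols))
      stop("no columns with intensity prefix '", intensityPrefix, "'")
    mat <- as.matrix(df[, intCols, drop = FALSE])
    colnames(mat) <- sub(paste0("^", intensityPrefix), "", intCols)
  }
  if (anyDuplicated(ids))
    stop("duplicate protein id(s): ",
         paste(unique(ids[duplicated(ids)])[1:min(5, sum(duplicated(ids)))],
               collapse = ", "))
  if (!is.numeric(mat)) {
    bad <- which(apply(df[, -1, drop = FALSE], 1,
                       function(r) any(is.na(suppressWarnings(as.numeric(r))))))
    stop("non-numeric intensities at data row(s): ",
         paste(head(bad, 5), collapse = ", "))
  }
  rownames(mat) <- ids
  makeSE(mat, parseSampleNames(colnames(mat)))
}

#' Write an abundance table as TSV
#'
#' First column `protein_id`, one column per sample named
#' `P<pop>_B<biorep>_T<techrep>`; round-trips through
#' [readAbundanceTable()].
#'
#' @param se the experiment.
#' @param path output file.
#' @param assay assay to write.
#' @export
writeAbundanceTable <- function(se, path, assay = "intensity") {
  x <- SummarizedExperiment::assay(se, assay)
  df <- data.frame(protein_id = rownames(x), x, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature-match table
#'
#' Native columns are `feature_id`, `matched`, `d_rt`, `d_mz`, `ppm_err`,
#' `is_decoy`. The `evidence` dialect ingests MaxQuant evidence-style
#' columns instead: `Match time difference`, `Match m/z difference` and
#' `Uncalibrated mass error [ppm]`, with a row counting as matched when its
#' match time difference is present.
#'
#' @param path TSV file.
#' @param dialect input dialect.
#' @param isDecoy decoy flag applied to all rows for the evidence dialect.
#' @return match `data.frame`.
#' @export
readMatchTable <- function(path, dialect = c("native", "evidence"),
                           isDecoy = FALSE) {
  dialect <- match.arg(dialect)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (dialect == "native") {
    checkMatchTable(df)
    df$matched <- as.logical(df$matched)
    df$is_decoy <- as.logical(df$is_decoy)
    return(df)
  }
  cols <- c(rt = "Match time difference", mz = "Match m/z difference",
            ppm = "Uncalibrated mass error [ppm]")
  if (!all(cols %in% names(df)))
    stop("evidence dialect requires columns: ",
         paste(cols[!cols %in% names(df)], collapse = ", "))
  data.frame(feature_id = sprintf("row_%06d", seq_len(nrow(df))),
             matched = !is.na(df[[cols[["rt"]]]]),
             d_rt = df[[cols[["rt"]]]], d_mz = df[[cols[["mz"]]]],
             ppm_err = df[[cols[["ppm"]]]], is_decoy = isDecoy)
}

#' Write a generic TSV
#'
#' @param df data frame.
#' @param path output file.
#' @export
writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize a signature model to a TSV + JSON bundle
#'
#' Writes `<prefix>_popmeans.tsv` and `<prefix>_ccs_profiles.tsv`
#' (populations / CCSs x proteins) and `<prefix>_model.json` with the
#' signature protein list and the population-to-CCS map.
#'
#' @param model a [SignatureModel-class].
#' @param prefix output path prefix.
#' @return the JSON path, invisibly.
#' @export
writeSignatureModel <- function(model, prefix) {
  pm <- popMeans(model)
  writeTsv(data.frame(population = rownames(pm), pm, check.names = FALSE),
           paste0(prefix, "_popmeans.tsv"))
  cp <- ccsProfiles(model)
  writeTsv(data.frame(ccs = rownames(cp), cp, check.names = FALSE),
           paste0(prefix, "_ccs_profiles.tsv"))
  jsonlite::write_json(
    list(psp_ids = pspIds(model),
         pop_to_ccs = as.list(popToCcs(model)),
         contiguous = model@contiguous),
    paste0(prefix, "_model.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(paste0(prefix, "_model.json"))
}

#' Read a signature model bundle written by [writeSignatureModel()]
#'
#' @param prefix the path prefix used when writing.
#' @return a [SignatureModel-class] (without the per-sample matrix, which
#'   is not needed for query assignment).
#' @export
readSignatureModel <- function(prefix) {
  js <- jsonlite::read_json(paste0(prefix, "_model.json"),
                            simplifyVector = TRUE)
  pm <- read.delim(paste0(prefix, "_popmeans.tsv"), check.names = FALSE)
  pmM <- as.matrix(pm[, -1, drop = FALSE])
  rownames(pmM) <- pm[[1]]
  cp <- read.delim(paste0(prefix, "_ccs_profiles.tsv"), check.names = FALSE)
  cpM <- as.matrix(cp[, -1, drop = FALSE])
  rownames(cpM) <- cp[[1]]
  new("SignatureModel", pspIds = js$psp_ids,
      sampleMatrix = matrix(numeric(0), 0, ncol(pmM),
                            dimnames = list(NULL, colnames(pmM))),
      popMeans = pmM, ccsProfiles = cpM,
      popToCcs = setNames(as.integer(unlist(js$pop_to_ccs)),
                          names(js$pop_to_ccs)),
      contiguous = isTRUE(js$contiguous))
}

#' Read a query proteome table
#'
#' TSV with columns `protein_id`, `value` and optionally `reference`;
#' duplicate ids are an error.
#'
#' @param path TSV file.
#' @return list with `values` (named numeric) and `reference` (named
#'   numeric or NULL).
#' @export
readQueryTable <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("protein_id", "value") %in% names(df)))
    stop("query table needs columns protein_id and value")
  if (anyDuplicated(df$protein_id))
    stop("duplicate protein id(s): ",
         df$protein_id[duplicated(df$protein_id)][1])
  values <- setNames(as.numeric(df$value), df$protein_id)
  reference <- if ("reference" %in% names(df))
    setNames(as.numeric(df$reference), df$protein_id) else NULL
  list(values = values, reference = reference)
}
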