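#' Read a gene-by-sample expression matrix from delimited text
#'
#' Expects genes in rows and samples in columns, a header row of sample
#' identifiers and a first column of gene identifiers (the layout public
#' cohort exports use). Values must be numeric and finite; missing genes
#' are represented by absence of the row, never by NA.
#'
#' @param path file path.
#' @param delimiter field separator; `"\t"` (default) or `","`.
#' @param scaleTag free-text label of the measurement scale (e.g.
#'   `"logFPKM"`, `"median-intensity"`), stored as an attribute.
#' @return numeric matrix with gene rownames and sample colnames, in file
#'   order, with attribute `scaleTag`.
#' @export
readExpression <- function(path, delimiter = "\t", scaleTag = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, sep = delimiter, header = TRUE,
                          check.names = FALSE, colClasses = "character",
                          quote = "\"", comment.char = "")
  genes <- df[[1L]]
  if (anyDuplicated(genes)) {
    dup <- genes[duplicated(genes)][1L]
    stop("duplicated gene identifier: ", dup)
  }
  samples <- colnames(df)[-1L]
  if (anyDuplicated(samples))
    stop("duplicated sample identifier: ",
         samples[duplicated(samples)][1L])
  vals <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  bad <- which(is.na(num) | !is.finite(num), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric or non-finite value at gene row %d ('%s'), sample column %d ('%s')",
                 bad[1, 1], genes[bad[1, 1]], bad[1, 2], samples[bad[1, 2]]))
  }
  dimnames(num) <- list(genes, samples)
  attr(num, "scaleTag") <- scaleTag
  num
}

#' Write an expression matrix as delimited text
#'
#' @param matrix numeric gene-by-sample matrix with dimnames.
#' @param path output path.
#' @param delimiter field separator.
#' @param idColumn name of the gene-identifier column in the header.
#' @export
writeExpression <- function(matrix, path, delimiter = "\t",
                            idColumn = "gene_id") {
  stopifnot(is.matrix(matrix), !is.null(rownames(matrix)),
            !is.null(colnames(matrix)))
  df <- data.frame(rownames(matrix), matrix, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- idColumn
  utils::write.table(df, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' MSigDB dialect: each line is set name, description, then gene
#' identifiers, tab-separated. The description is discarded and duplicate
#' genes within a set are collapsed, preserving first-occurrence order.
#'
#' @param path file path.
#' @return named list of character vectors (the layout gene-set tools such
#'   as fgsea consume).
#' @export
readGmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop(sprintf("GMT line %d has fewer than 3 fields", i))
    nm <- f[1L]
    if (nm %in% names(sets))
      stop("duplicated gene-set name: ", nm)
    genes <- unique(f[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (!length(genes))
      stop(sprintf("GMT line %d ('%s') has no genes", i, nm))
    sets[[nm]] <- genes
  }
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description description field written for every set.
#' @export
writeGmt <- function(sets, path, description = "na") {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, description, sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a plain-text gene list (one identifier per line)
#'
#' Used for the stable-gene panel. Blank lines and lines starting with `#`
#' are ignored.
#'
#' @param path file path.
#' @return character vector.
#' @export
readGeneList <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x <- x[nzchar(x) & !startsWith(x, "#")]
  if (anyDuplicated(x))
    stop("duplicated gene identifier: ", x[duplicated(x)][1L])
  x
}

.MODEL_FORMAT <- "ember-model/1"

#' Serialize an embedding model to JSON
#'
#' The model is written as a single human-inspectable JSON document (gene
#' lists, loadings as nested arrays of 17-significant-digit decimals, sign
#' anchors and training metadata). [loadModel()] restores it
#' bit-compatibly.
#'
#' @param model an [EmberModel-class] or [AsisModel-class].
#' @param path output path.
#' @export
saveModel <- function(model, path) {
  stopifnot(is(model, "EmberModel"))
  validObject(model)
  doc <- list(
    format = .MODEL_FORMAT,
    class = class(model)[1L],
    featureGenes = model@featureGenes,
    stableGenes = model@stableGenes,
    componentLabels = colnames(model@loadings),
    ## decimal strings with 17 significant digits: doubles round-trip
    ## exactly, which plain JSON numbers do not guarantee
    loadings = lapply(seq_len(ncol(model@loadings)), function(k)
      sprintf("%.17g", model@loadings[, k])),
    signAnchors = model@signAnchors,
    trainingInfo = model@trainingInfo
  )
  if (is(model, "AsisModel"))
    doc$batchComponents <- model@batchComponents
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE,
                       pretty = FALSE)
  invisible(path)
}

#' Load an embedding model from JSON
#'
#' @param path path written by [saveModel()].
#' @return the restored [EmberModel-class] (or [AsisModel-class]).
#' @export
loadModel <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    stop("cannot parse model file (truncated or not JSON): ",
                         conditionMessage(e)))
  if (is.null(doc$format) || !identical(doc$format, .MODEL_FORMAT))
    stop("model format tag mismatch: expected '", .MODEL_FORMAT,
         "', found '", doc$format %||% "<missing>", "'")
  if (is.null(doc$loadings))
    stop("model file has no loadings block")
  ## columns were written as a JSON array of arrays of decimal strings;
  ## simplifyVector turns that into a components-by-genes matrix (or a
  ## list on ragged input)
  L <- if (is.matrix(doc$loadings)) t(apply(doc$loadings, c(1, 2), as.numeric))
       else do.call(cbind, lapply(doc$loadings, as.numeric))
  dimnames(L) <- list(doc$featureGenes, doc$componentLabels)
  anchors <- as.data.frame(doc$signAnchors, stringsAsFactors = FALSE)
  ti <- doc$trainingInfo
  if (is.null(ti)) ti <- list()
  cls <- doc$class %||% "EmberModel"
  if (identical(cls, "AsisModel")) {
    m <- new("AsisModel", featureGenes = doc$featureGenes,
             stableGenes = doc$stableGenes, loadings = L,
             signAnchors = anchors, trainingInfo = as.list(ti),
             batchComponents = as.integer(doc$batchComponents))
  } else {
    m <- new("EmberModel", featureGenes = doc$featureGenes,
             stableGenes = doc$stableGenes, loadings = L,
             signAnchors = anchors, trainingInfo = as.list(ti))
  }
  validObject(m)
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
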