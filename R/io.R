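#' Read a square kinship matrix from delimited text
#'
#' Reads a CSV/TSV file holding an n x n relationship matrix keyed by row
#' order (a header row of column names is allowed; a leading `row` id
#' column, as written by mixed-model software, is dropped).
#'
#' @param path file path.
#' @param normalized logical; assert/record trace = n after reading.  When
#'   TRUE and the trace differs from n the matrix is rescaled.
#' @return a [KinshipMatrix-class].
#' @export
readKinship <- function(path, normalized = TRUE) {
  tab <- utils::read.table(path, header = TRUE, sep = guessSep(path),
                           check.names = FALSE)
  drop <- tolower(names(tab)) %in% c("parm", "row", "id")
  tab <- tab[, !drop, drop = FALSE]
  K <- as.matrix(tab)
  if (nrow(K) != ncol(K))
    stop("kinship file is not square: ", nrow(K), " x ", ncol(K))
  storage.mode(K) <- "double"
  dimnames(K) <- NULL
  if (normalized) normalizeKinship(K) else kinshipMatrix(K)
}

#' Read a marker map
#'
#' Expects columns `marker`, `chromosome`, `position` (cM); extra columns
#' are kept.  Rows are sorted by chromosome then position; ties in position
#' within a chromosome are an error.
#'
#' @param path file path.
#' @return data.frame sorted by chromosome then cM position.
#' @export
readMarkerMap <- function(path) {
  map <- utils::read.table(path, header = TRUE, sep = guessSep(path),
                           stringsAsFactors = FALSE)
  need <- c("marker", "chromosome", "position")
  if (!all(need %in% names(map)))
    stop("map file must have columns: ", paste(need, collapse = ", "))
  map <- map[order(map$chromosome, map$position), , drop = FALSE]
  dup <- unlist(tapply(map$position, map$chromosome,
                       function(p) duplicated(p)))
  if (any(dup)) stop("duplicated cM positions within a chromosome")
  rownames(map) <- NULL
  map
}

#' Read aligned phenotype/genotype/kinship/map tables
#'
#' Loads the delimited-text inputs of a QTL analysis and aligns them by
#' individual.  The phenotype file must hold an `id` column, one trait
#' column (`trait` argument) and optional covariate columns; the genotype
#' file an `id` column plus one column per marker coded \{+1, 0, -1\}.
#' Individuals are matched on id; order follows the phenotype file.  The
#' kinship file is keyed by row order and must match the phenotype file's
#' individual count and order.
#'
#' @param pheno_path phenotype file (CSV/TSV, header row).
#' @param geno_path genotype file (CSV/TSV, header row, \{+1,0,-1\} codes).
#' @param kinship_path optional square kinship file.
#' @param map_path optional marker map file.
#' @param trait name of the trait column (default `"y"`).
#' @param covariates character vector of covariate column names in the
#'   phenotype file (default none).
#' @return list with elements `trait` (numeric vector), `covariates`
#'   (numeric matrix or NULL), `genotypes` (named list of
#'   [GenotypeVector-class]), `kinship` ([KinshipMatrix-class] or NULL),
#'   `map` (data.frame or NULL), `ids` (character).
#' @export
readQTLTables <- function(pheno_path, geno_path, kinship_path = NULL,
                          map_path = NULL, trait = "y", covariates = NULL) {
  pheno <- utils::read.table(pheno_path, header = TRUE,
                             sep = guessSep(pheno_path),
                             stringsAsFactors = FALSE)
  geno <- utils::read.table(geno_path, header = TRUE,
                            sep = guessSep(geno_path),
                            stringsAsFactors = FALSE)
  if (!"id" %in% names(pheno)) stop("phenotype file needs an 'id' column")
  if (!"id" %in% names(geno)) stop("genotype file needs an 'id' column")
  if (!trait %in% names(pheno))
    stop("trait column '", trait, "' not found in phenotype file")
  ids <- as.character(pheno$id)
  gidx <- match(ids, as.character(geno$id))
  if (anyNA(gidx))
    stop("genotype file is missing ", sum(is.na(gidx)), " individual(s)")
  geno <- geno[gidx, setdiff(names(geno), "id"), drop = FALSE]
  bad <- !vapply(geno, function(g) all(g %in% c(-1, 0, 1) | is.na(g)),
                 logical(1))
  if (any(bad))
    stop("unreadable genotype codes in marker(s): ",
         paste(names(geno)[bad], collapse = ", "))
  gvecs <- lapply(names(geno), function(m) genotypeVector(geno[[m]], id = m))
  names(gvecs) <- names(geno)
  covmat <- NULL
  if (length(covariates)) {
    miss <- setdiff(covariates, names(pheno))
    if (length(miss))
      stop("covariate column(s) not found: ", paste(miss, collapse = ", "))
    covmat <- as.matrix(pheno[, covariates, drop = FALSE])
    storage.mode(covmat) <- "double"
  }
  kin <- NULL
  if (!is.null(kinship_path)) {
    kin <- readKinship(kinship_path)
    if (nrow(kin) != length(ids))
      stop("kinship dimension ", nrow(kin),
           " does not match sample size ", length(ids))
  }
  map <- if (!is.null(map_path)) readMarkerMap(map_path) else NULL
  list(trait = as.numeric(pheno[[trait]]), covariates = covmat,
       genotypes = gvecs, kinship = kin, map = map, ids = ids)
}

#' Write a genome-scan result table to TSV
#'
#' @param rows data.frame as returned by [genomeScan()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
writeScanTSV <- function(rows, path) {
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# sniff the delimiter from the header line
guessSep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}
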