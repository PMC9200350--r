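#' @importFrom Matrix readMM writeMM colSums rowSums t sparseMatrix
#' @importFrom methods as is
#' @importFrom utils read.delim write.table
NULL

sc_log <- function(...) message("[scpipeline] ", sprintf(...))

sc_stop <- function(class, ...) {
  stop(structure(class = c(class, "scpipeline_error", "error", "condition"),
                 list(message = sprintf(...), call = sys.call(-1))))
}

#' Construct a count matrix container
#'
#' Bundles a sparse non-negative integer gene-by-cell UMI count matrix with
#' per-gene annotations (id, symbol, biotype, mitochondrial and ribosomal
#' flags) and per-cell barcodes, validating the basic integrity invariants.
#'
#' @param counts sparse or dense non-negative matrix, genes in rows.
#' @param genes data.frame with columns `gene_id`, `symbol`, `biotype`,
#'   `is_mito`, `is_ribo`; one row per matrix row.
#' @param barcodes character vector of unique cell barcodes, one per column.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, genes, barcodes) {
  counts <- as(as(counts, "CsparseMatrix"), "generalMatrix")
  if (any(counts@x < 0)) sc_stop("integrity_error", "count matrix has negative entries")
  if (nrow(genes) != nrow(counts))
    sc_stop("integrity_error", "gene table has %d rows but matrix has %d", nrow(genes), nrow(counts))
  if (length(barcodes) != ncol(counts))
    sc_stop("integrity_error", "%d barcodes but matrix has %d columns", length(barcodes), ncol(counts))
  if (anyDuplicated(genes$gene_id)) sc_stop("integrity_error", "duplicate gene ids")
  if (anyDuplicated(barcodes)) sc_stop("integrity_error", "duplicate barcodes")
  needed <- c("gene_id", "symbol", "biotype", "is_mito", "is_ribo")
  miss <- setdiff(needed, names(genes))
  if (length(miss)) sc_stop("integrity_error", "gene table lacks column(s): %s", paste(miss, collapse = ", "))
  rownames(counts) <- genes$gene_id
  colnames(counts) <- barcodes
  structure(list(counts = counts, genes = genes, barcodes = barcodes),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d cells, %d nonzero entries\n",
              nrow(x$counts), ncol(x$counts), length(x$counts@x)))
  cat(sprintf("  mito genes: %d, ribo genes: %d\n", sum(x$genes$is_mito), sum(x$genes$is_ribo)))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Read a 10x Genomics-style MTX triplet directory
#'
#' Expects a MatrixMarket coordinate file plus a barcodes file and a features
#' file with at least three tab-separated columns (id, symbol, biotype).
#' Mitochondrial and ribosomal genes are flagged by symbol prefix.
#'
#' @param dir_path directory holding `matrix.mtx`, `barcodes.tsv`, `features.tsv`.
#' @param mito_prefix symbol prefix marking mitochondrial genes.
#' @param ribo_prefixes symbol prefixes marking ribosomal-protein genes.
#' @return A [count_matrix()].
#' @export
read_10x_mtx <- function(dir_path, mito_prefix = "MT-", ribo_prefixes = c("RPS", "RPL")) {
  paths <- file.path(dir_path, c("matrix.mtx", "barcodes.tsv", "features.tsv"))
  names(paths) <- basename(paths)
  for (p in paths) if (!file.exists(p))
    sc_stop("format_error", "missing required file: %s", p)
  header <- read_mtx_header(paths[["matrix.mtx"]])
  m <- Matrix::readMM(paths[["matrix.mtx"]])
  if (nrow(m) != header[1] || ncol(m) != header[2])
    sc_stop("integrity_error", "matrix dimensions disagree with MTX header")
  ntrip <- count_mtx_entries(paths[["matrix.mtx"]])
  if (ntrip != header[3])
    sc_stop("integrity_error",
            "MTX header declares %d entries but file has %d", header[3], ntrip)
  barcodes <- readLines(paths[["barcodes.tsv"]])
  if (length(barcodes) != ncol(m))
    sc_stop("integrity_error", "barcodes file has %d entries for %d columns",
            length(barcodes), ncol(m))
  if (anyDuplicated(barcodes)) sc_stop("integrity_error", "duplicate barcode in barcodes file")
  feats <- utils::read.delim(paths[["features.tsv"]], header = FALSE,
                             stringsAsFactors = FALSE)
  if (ncol(feats) < 3)
    sc_stop("format_error", "features file must have >= 3 columns (id, symbol, biotype)")
  if (nrow(feats) != nrow(m))
    sc_stop("integrity_error", "features file has %d rows for %d matrix rows",
            nrow(feats), nrow(m))
  genes <- data.frame(
    gene_id = as.character(feats[[1]]),
    symbol = as.character(feats[[2]]),
    biotype = as.character(feats[[3]]),
    stringsAsFactors = FALSE
  )
  genes$is_mito <- startsWith(genes$symbol, mito_prefix)
  genes$is_ribo <- Reduce(`|`, lapply(ribo_prefixes, function(p) startsWith(genes$symbol, p)))
  count_matrix(m, genes, barcodes)
}

read_mtx_header <- function(path) {
  con <- file(path, "r"); on.exit(close(con))
  repeat {
    line <- readLines(con, n = 1)
    if (!length(line)) sc_stop("format_error", "no size header in %s", path)
    if (!startsWith(line, "%")) break
  }
  as.integer(strsplit(trimws(line), "\\s+")[[1]])
}

count_mtx_entries <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "%") & nzchar(trimws(lines))]
  length(body) - 1L  # first non-comment line is the size header
}

#' Write a count matrix as a 10x-style MTX triplet
#'
#' Inverse of [read_10x_mtx()]: writes `matrix.mtx`, `barcodes.tsv` and a
#' `features.tsv` carrying id, symbol and biotype columns.
#'
#' @param m a [count_matrix()].
#' @param dir_path output directory (created if absent).
#' @export
write_10x_mtx <- function(m, dir_path) {
  dir.create(dir_path, showWarnings = FALSE, recursive = TRUE)
  cm <- m$counts
  dimnames(cm) <- NULL
  Matrix::writeMM(cm, file.path(dir_path, "matrix.mtx"))
  writeLines(m$barcodes, file.path(dir_path, "barcodes.tsv"))
  utils::write.table(m$genes[, c("gene_id", "symbol", "biotype")],
                     file.path(dir_path, "features.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(dir_path)
}

#' Read a hierarchical cell-type marker list
#'
#' Tab-separated file with columns `level` (major/sub), `name`, `parent`
#' (empty for major types) and `genes` (comma-separated marker symbols).
#' Every subtype's parent must be a defined major type, marker sets must be
#' non-empty, and names unique within a level.
#'
#' @param path marker TSV path.
#' @return A `marker_hierarchy`: list with `major` (named list of character
#'   vectors) and `sub` (named list, per major type, of named lists).
#' @export
read_marker_hierarchy <- function(path) {
  if (!file.exists(path)) sc_stop("format_error", "missing marker file: %s", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  needed <- c("level", "name", "parent", "genes")
  if (!all(needed %in% names(tab)))
    sc_stop("format_error", "marker file must have columns: %s", paste(needed, collapse = ", "))
  parse_genes <- function(s) {
    g <- trimws(strsplit(s, ",")[[1]])
    g[nzchar(g)]
  }
  major <- list(); sub <- list()
  for (i in seq_len(nrow(tab))) {
    genes <- parse_genes(tab$genes[i])
    if (!length(genes))
      sc_stop("validation_error", "empty marker set for type '%s'", tab$name[i])
    if (tab$level[i] == "major") {
      if (tab$name[i] %in% names(major))
        sc_stop("validation_error", "duplicate major type '%s'", tab$name[i])
      major[[tab$name[i]]] <- unique(genes)
    } else if (tab$level[i] == "sub") {
      p <- tab$parent[i]
      if (!nzchar(p)) sc_stop("validation_error", "subtype '%s' has no parent", tab$name[i])
      if (tab$name[i] %in% names(sub[[p]]))
        sc_stop("validation_error", "duplicate subtype '%s'", tab$name[i])
      sub[[p]] <- c(sub[[p]], stats::setNames(list(unique(genes)), tab$name[i]))
    } else sc_stop("validation_error", "unknown level '%s' (row %d)", tab$level[i], i)
  }
  undefined <- setdiff(names(sub), names(major))
  if (length(undefined))
    sc_stop("validation_error", "subtype parent(s) not defined as major: %s",
            paste(undefined, collapse = ", "))
  marker_hierarchy(major, sub)
}

#' Construct a marker hierarchy in code
#'
#' @param major named list mapping major type name to marker symbol vector.
#' @param sub named list mapping a major type name to a named list of
#'   subtype marker vectors. May be empty.
#' @export
marker_hierarchy <- function(major, sub = list()) {
  if (!length(major)) sc_stop("validation_error", "no major cell types defined")
  if (any(!lengths(major))) sc_stop("validation_error", "empty marker set among major types")
  bad <- setdiff(names(sub), names(major))
  if (length(bad))
    sc_stop("validation_error", "subtype parent(s) not defined as major: %s",
            paste(bad, collapse = ", "))
  for (p in names(sub)) if (any(!lengths(sub[[p]])))
    sc_stop("validation_error", "empty marker set among subtypes of %s", p)
  structure(list(major = major, sub = sub), class = "marker_hierarchy")
}

#' @export
print.marker_hierarchy <- function(x, ...) {
  cat(sprintf("marker_hierarchy: %d major types (%s)\n",
              length(x$major), paste(names(x$major), collapse = ", ")))
  for (p in names(x$sub))
    cat(sprintf("  %s -> %s\n", p, paste(names(x$sub[[p]]), collapse = ", ")))
  invisible(x)
}

#' Read gene sets in GMT format
#'
#' One set per tab-separated line: name, description, then gene symbols.
#' Duplicate genes within a set are deduplicated; duplicate set names are an
#' error.
#'
#' @param path GMT file path.
#' @return Named list mapping set name to a character vector of symbols.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) sc_stop("format_error", "missing GMT file: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      sc_stop("format_error", "GMT line %d has %d fields (need >= 3)", i, length(f))
    nm <- f[1]
    if (nm %in% names(sets))
      sc_stop("format_error", "duplicate gene set name '%s' (line %d)", nm, i)
    sets[[nm]] <- unique(f[-(1:2)])
  }
  sets
}

#' Write gene sets in GMT format
#' @param sets named list of gene symbol vectors.
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "na", sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read offline drug-gene interaction and clinical-evidence snapshots
#'
#' The interaction table is undirected (gene, drug, interaction_type, source);
#' the evidence table carries the expression direction (overexpression /
#' underexpression) and clinical significance (sensitivity / resistance) used
#' to direct the candidates. Enumerated fields are normalized to lower case.
#'
#' @param interactions_path TSV with header gene, drug, interaction_type, source.
#' @param evidence_path TSV with header gene, drug, expression_direction,
#'   clinical_significance, evidence_source.
#' @return A list of class `interaction_snapshot` with data.frames
#'   `interactions` and `evidence`.
#' @export
read_interaction_snapshot <- function(interactions_path, evidence_path) {
  for (p in c(interactions_path, evidence_path))
    if (!file.exists(p)) sc_stop("format_error", "missing snapshot file: %s", p)
  inter <- utils::read.delim(interactions_path, stringsAsFactors = FALSE,
                             colClasses = "character")
  evid <- utils::read.delim(evidence_path, stringsAsFactors = FALSE,
                            colClasses = "character")
  need_i <- c("gene", "drug", "interaction_type", "source")
  need_e <- c("gene", "drug", "expression_direction", "clinical_significance",
              "evidence_source")
  if (!all(need_i %in% names(inter)))
    sc_stop("format_error", "interactions file needs columns: %s", paste(need_i, collapse = ", "))
  if (!all(need_e %in% names(evid)))
    sc_stop("format_error", "evidence file needs columns: %s", paste(need_e, collapse = ", "))
  check_nonempty <- function(df, what) {
    bad <- which(!nzchar(df$gene) | !nzchar(df$drug))
    if (length(bad))
      sc_stop("validation_error", "%s row %d has empty gene or drug", what, bad[1])
  }
  check_nonempty(inter, "interactions"); check_nonempty(evid, "evidence")
  evid$expression_direction <- tolower(evid$expression_direction)
  evid$clinical_significance <- tolower(evid$clinical_significance)
  bad_dir <- which(!evid$expression_direction %in% c("overexpression", "underexpression"))
  if (length(bad_dir))
    sc_stop("validation_error", "evidence row %d: unknown expression_direction '%s'",
            bad_dir[1], evid$expression_direction[bad_dir[1]])
  bad_sig <- which(!evid$clinical_significance %in% c("sensitivity", "resistance"))
  if (length(bad_sig))
    sc_stop("validation_error", "evidence row %d: unknown clinical_significance '%s'",
            bad_sig[1], evid$clinical_significance[bad_sig[1]])
  structure(list(interactions = inter, evidence = evid),
            class = "interaction_snapshot")
}

#' @export
print.interaction_snapshot <- function(x, ...) {
  cat(sprintf("interaction_snapshot: %d interactions, %d evidence records\n",
              nrow(x$interactions), nrow(x$evidence)))
  invisible(x)
}

rbind_rows <- function(rows) {
  if (!length(rows)) return(NULL)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
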