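# Readers, writers and validators for the three kinds of input:
# phylogenetic trees (Newick), distance matrices and binary
# host-parasite association tables.

#' Read and validate a phylogenetic tree from Newick
#'
#' Thin wrapper around [ape::read.tree()] that enforces the invariants the
#' downstream distance computations rely on: at least two tips, unique tip
#' labels and a finite, non-negative length on every edge.
#'
#' @param source Path to a Newick file, or a Newick string.
#' @param assume_unit_lengths If `TRUE`, a tree without branch lengths is
#'   accepted and every edge is assigned length 1. Otherwise missing branch
#'   lengths are an error.
#' @return An object of class `"phylo"`.
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);")
#' patristic_distances(tr)
#' @export
read_newick <- function(source, assume_unit_lengths = FALSE) {
  stopifnot(is.character(source), length(source) == 1L)
  tree <- if (file.exists(source) && !grepl("\\(", source)) {
    tryCatch(ape::read.tree(file = source),
             error = function(e) stop("failed to parse Newick file '", source,
                                      "': ", conditionMessage(e), call. = FALSE))
  } else {
    tryCatch(ape::read.tree(text = source),
             error = function(e) stop("failed to parse Newick string: ",
                                      conditionMessage(e), call. = FALSE))
  }
  if (is.null(tree)) stop("failed to parse Newick input", call. = FALSE)
  validate_tree(tree, assume_unit_lengths = assume_unit_lengths)
}

validate_tree <- function(tree, assume_unit_lengths = FALSE) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object", call. = FALSE)
  n_tip <- length(tree$tip.label)
  if (n_tip < 2L) stop("tree has fewer than 2 tips", call. = FALSE)
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "), call. = FALSE)
  if (is.null(tree$edge.length)) {
    if (!assume_unit_lengths)
      stop("tree has no branch lengths (set assume_unit_lengths = TRUE ",
           "to treat every edge as length 1)", call. = FALSE)
    tree$edge.length <- rep(1, nrow(tree$edge))
  }
  if (anyNA(tree$edge.length) || any(!is.finite(tree$edge.length)))
    stop("tree has missing or non-finite branch lengths", call. = FALSE)
  if (any(tree$edge.length < 0))
    stop("tree has negative branch lengths", call. = FALSE)
  tree
}

#' Patristic distance matrix of a tree
#'
#' Sum of branch lengths along the path between every pair of tips,
#' returned as a labelled symmetric matrix in tip-label order.
#'
#' @param tree A `"phylo"` object with branch lengths.
#' @inheritParams read_newick
#' @return A square numeric matrix with tip labels as dimnames.
#' @export
patristic_distances <- function(tree, assume_unit_lengths = FALSE) {
  tree <- validate_tree(tree, assume_unit_lengths = assume_unit_lengths)
  d <- stats::cophenetic(tree)
  d <- d[tree$tip.label, tree$tip.label]
  validate_distance_matrix(d)
}

#' Validate (and lightly repair) a distance matrix
#'
#' Checks squareness, labels, non-negativity, a zero diagonal and symmetry.
#' Asymmetries below `tol` (relative to the largest entry) are averaged
#' away; anything larger is an error.
#'
#' @param d A square numeric matrix with matching row/column labels.
#' @param tol Relative symmetry/diagonal tolerance.
#' @return The validated, exactly symmetric matrix.
#' @export
validate_distance_matrix <- function(d, tol = 1e-10) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || !is.numeric(d)) stop("distances must be a numeric matrix", call. = FALSE)
  if (nrow(d) != ncol(d)) stop("distance matrix is not square", call. = FALSE)
  if (nrow(d) < 2L) stop("distance matrix needs at least 2 taxa", call. = FALSE)
  if (is.null(rownames(d)) && is.null(colnames(d)))
    stop("distance matrix has no taxon labels", call. = FALSE)
  if (is.null(rownames(d))) rownames(d) <- colnames(d)
  if (is.null(colnames(d))) colnames(d) <- rownames(d)
  if (!identical(rownames(d), colnames(d)))
    stop("row and column labels of the distance matrix differ", call. = FALSE)
  if (anyDuplicated(rownames(d)))
    stop("duplicate taxon labels in distance matrix", call. = FALSE)
  if (anyNA(d) || any(!is.finite(d))) stop("non-finite distances", call. = FALSE)
  if (any(d < 0)) stop("negative distances", call. = FALSE)
  scale <- max(d, 1e-300)
  if (any(abs(diag(d)) > tol * scale))
    stop("distance matrix has a non-zero diagonal", call. = FALSE)
  asym <- max(abs(d - t(d)))
  if (asym > tol * scale)
    stop("distance matrix is asymmetric (max |d - t(d)| = ",
         format(asym), ")", call. = FALSE)
  d <- (d + t(d)) / 2
  diag(d) <- 0
  d
}

#' Read a distance matrix from CSV, TSV or square PHYLIP
#'
#' @param path File path.
#' @param format `"auto"` guesses from the extension (`.csv`, `.tsv`/`.txt`,
#'   `.phy`/`.phylip`/`.dist`); otherwise one of `"csv"`, `"tsv"`,
#'   `"phylip"`. The PHYLIP reader accepts the relaxed square format: a
#'   leading taxon-count line, then one whitespace-separated row per taxon
#'   starting with its label.
#' @return A validated labelled distance matrix.
#' @export
read_distance_matrix <- function(path, format = c("auto", "csv", "tsv", "phylip")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
                     csv = "csv",
                     tsv = , txt = "tsv",
                     phy = , phylip = , dist = "phylip",
                     stop("cannot guess distance-matrix format from extension '",
                          ext, "'", call. = FALSE))
  }
  d <- switch(format,
    csv = ,
    tsv = {
      sep <- if (format == "csv") "," else "\t"
      x <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                             check.names = FALSE, stringsAsFactors = FALSE)
      as.matrix(x)
    },
    phylip = read_phylip_square(path)
  )
  if (!is.numeric(d)) stop("non-numeric entries in distance matrix", call. = FALSE)
  validate_distance_matrix(d)
}

read_phylip_square <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  m <- suppressWarnings(as.integer(trimws(lines[1L])))
  if (is.na(m)) stop("PHYLIP file must start with the taxon count", call. = FALSE)
  if (length(lines) < m + 1L) stop("PHYLIP file truncated", call. = FALSE)
  rows <- lapply(lines[seq_len(m) + 1L], function(l) strsplit(trimws(l), "\\s+")[[1]])
  labels <- vapply(rows, `[`, character(1), 1L)
  vals <- lapply(rows, function(r) suppressWarnings(as.numeric(r[-1L])))
  if (any(lengths(vals) != m))
    stop("PHYLIP rows must each contain ", m, " distances", call. = FALSE)
  d <- do.call(rbind, vals)
  dimnames(d) <- list(labels, labels)
  d
}

#' Write a distance matrix
#'
#' Writes with 10 significant digits so that read/write round-trips are
#' lossless at text precision.
#'
#' @inheritParams read_distance_matrix
#' @param d Labelled distance matrix.
#' @export
write_distance_matrix <- function(d, path, format = c("csv", "tsv", "phylip")) {
  format <- match.arg(format)
  d <- validate_distance_matrix(d)
  fmt <- function(x) formatC(x, digits = 10, format = "g")
  if (format == "phylip") {
    rows <- vapply(seq_len(nrow(d)), function(i) {
      paste(c(rownames(d)[i], fmt(d[i, ])), collapse = " ")
    }, character(1))
    writeLines(c(as.character(nrow(d)), rows), path)
  } else {
    sep <- if (format == "csv") "," else "\t"
    out <- cbind(rownames(d), matrix(fmt(d), nrow(d)))
    header <- paste(c("", colnames(d)), collapse = sep)
    writeLines(c(header, apply(out, 1, paste, collapse = sep)), path)
  }
  invisible(path)
}

#' Construct a validated host-parasite association matrix
#'
#' The association matrix `A` is an `h x p` binary table, hosts as rows and
#' parasites as columns, with 1 marking an observed host-parasite link.
#'
#' Hosts without links are tolerated (they contribute no rows after link
#' expansion); parasites without links cannot be placed in the expanded
#' parasite configuration and are rejected in observed data, but may arise
#' legitimately in row-permuted matrices.
#'
#' @param x A numeric/logical matrix of 0s and 1s with row and column names.
#' @param allow_empty_parasites Tolerate all-zero parasite columns (used for
#'   permuted matrices).
#' @param empty_hosts One of `"warn"`, `"error"`, `"ok"`: what to do about
#'   all-zero host rows.
#' @return An integer matrix of class `"association_matrix"`.
#' @examples
#' A <- association_matrix(matrix(c(1, 0, 1, 0, 1, 1), 3, 2, byrow = TRUE,
#'                         dimnames = list(c("H1", "H2", "H3"), c("P1", "P2"))))
#' association_links(A)
#' @export
association_matrix <- function(x, allow_empty_parasites = FALSE,
                               empty_hosts = c("warn", "error", "ok")) {
  empty_hosts <- match.arg(empty_hosts)
  if (!is.matrix(x)) stop("association data must be a matrix", call. = FALSE)
  if (nrow(x) == 0L || ncol(x) == 0L) stop("empty association matrix", call. = FALSE)
  if (is.logical(x)) x[] <- as.integer(x)
  if (!is.numeric(x) || anyNA(x) || !all(x %in% c(0, 1)))
    stop("association cells must all be 0 or 1", call. = FALSE)
  if (is.null(rownames(x))) rownames(x) <- paste0("H", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("P", seq_len(ncol(x)))
  if (anyDuplicated(rownames(x)) || anyDuplicated(colnames(x)))
    stop("duplicate host or parasite labels", call. = FALSE)
  storage.mode(x) <- "integer"
  if (sum(x) < 1L) stop("association matrix contains no links", call. = FALSE)
  if (!allow_empty_parasites && any(colSums(x) == 0L))
    stop("parasite(s) without any host link: ",
         paste(colnames(x)[colSums(x) == 0L], collapse = ", "), call. = FALSE)
  if (any(rowSums(x) == 0L) && empty_hosts != "ok") {
    msg <- paste0("host(s) without any parasite link: ",
                  paste(rownames(x)[rowSums(x) == 0L], collapse = ", "))
    if (empty_hosts == "error") stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  class(x) <- c("association_matrix", class(x))
  x
}

#' @export
print.association_matrix <- function(x, ...) {
  cat("Host-parasite association matrix: ", nrow(x), " hosts x ", ncol(x),
      " parasites, ", sum(x), " links\n", sep = "")
  print(unclass(x), ...)
  invisible(x)
}

#' Ordered link list of an association matrix
#'
#' Links are enumerated row-major (host by host, parasites in column
#' order), the order used throughout for link expansion and residuals.
#'
#' @param A An [association_matrix()] (or coercible binary matrix).
#' @return A tibble with columns `host`, `parasite`, `host_idx`, `par_idx`,
#'   one row per link.
#' @export
association_links <- function(A) {
  A <- as_association(A, allow_empty_parasites = TRUE, empty_hosts = "ok")
  idx <- which(t(unclass(A)) == 1L)             # row-major enumeration
  par_idx <- (idx - 1L) %% ncol(A) + 1L
  host_idx <- (idx - 1L) %/% ncol(A) + 1L
  tibble(host = rownames(A)[host_idx], parasite = colnames(A)[par_idx],
         host_idx = host_idx, par_idx = par_idx)
}

as_association <- function(A, ...) {
  if (inherits(A, "association_matrix")) A else association_matrix(as.matrix(A), ...)
}

#' Read a binary association table from CSV/TSV
#'
#' @param path File path; `.csv` is comma-separated, anything else is read
#'   as tab-separated. First column holds host labels, header the parasite
#'   labels.
#' @param transpose Set `TRUE` when the file stores parasites as rows (the
#'   orientation of the original ParaFit paper); the table is transposed to
#'   the hosts-as-rows convention used here.
#' @inheritParams association_matrix
#' @return An [association_matrix()].
#' @export
read_association_matrix <- function(path, transpose = FALSE,
                                    allow_empty_parasites = FALSE,
                                    empty_hosts = "warn") {
  sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  x <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                         check.names = FALSE, stringsAsFactors = FALSE)
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("association cells must be numeric 0/1", call. = FALSE)
  if (transpose) x <- t(x)
  association_matrix(x, allow_empty_parasites = allow_empty_parasites,
                     empty_hosts = empty_hosts)
}

#' Write an association matrix to CSV/TSV
#'
#' @param A An [association_matrix()].
#' @param path Output path; `.csv` gets commas, otherwise tabs.
#' @export
write_association_matrix <- function(A, path) {
  A <- as_association(A, allow_empty_parasites = TRUE, empty_hosts = "ok")
  sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  header <- paste(c("", colnames(A)), collapse = sep)
  rows <- vapply(seq_len(nrow(A)), function(i) {
    paste(c(rownames(A)[i], A[i, ]), collapse = sep)
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Align distance matrices to an association matrix
#'
#' Reorders and subsets the host and parasite distance matrices to exactly
#' the label order of `A`. Taxa present in a distance matrix but absent
#' from `A` are pruned with a warning; labels of `A` missing from their
#' distance matrix are an error.
#'
#' @param host_d,par_d Labelled distance matrices (or `"phylo"` trees,
#'   converted via [patristic_distances()]).
#' @param A An [association_matrix()].
#' @return A list with elements `host_d`, `par_d`, `A`.
#' @export
align_labels <- function(host_d, par_d, A) {
  if (inherits(host_d, "phylo")) host_d <- patristic_distances(host_d)
  if (inherits(par_d, "phylo")) par_d <- patristic_distances(par_d)
  host_d <- validate_distance_matrix(host_d)
  par_d <- validate_distance_matrix(par_d)
  A <- as_association(A, allow_empty_parasites = TRUE, empty_hosts = "ok")
  align_one <- function(d, labels, what) {
    missing <- setdiff(labels, rownames(d))
    if (length(missing))
      stop(what, " label(s) in the association matrix missing from the ",
           what, " distance matrix: ", paste(missing, collapse = ", "),
           call. = FALSE)
    extra <- setdiff(rownames(d), labels)
    if (length(extra))
      warning("pruning ", length(extra), " ", what,
              " taxa absent from the association matrix: ",
              paste(extra, collapse = ", "), call. = FALSE)
    d[labels, labels, drop = FALSE]
  }
  list(host_d = align_one(host_d, rownames(A), "host"),
       par_d = align_one(par_d, colnames(A), "parasite"),
       A = A)
}
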