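#' Annotated protein-protein interaction network
#'
#' Container for a PPI network together with flat Gene Ontology annotations:
#' the protein set, a symmetric binary adjacency matrix, a per-protein table of
#' (category, value) annotation pairs, and the catalog of annotation categories
#' with their admissible values.
#'
#' @param proteins character vector of unique protein identifiers. Stored
#'   sorted; identifiers are opaque, case-sensitive strings.
#' @param adjacency square 0/1 matrix (rows/columns in `proteins` order after
#'   sorting, or carrying dimnames that will be reordered). Must be symmetric
#'   with a zero diagonal.
#' @param annotations data frame with character columns `protein`, `category`,
#'   `value`; zero-row data frame for an unannotated network.
#' @param catalog a [go_catalog()]; built from `annotations` when `NULL`.
#'
#' @return An object of class `annotated_network`: a list with elements
#'   `proteins`, `adjacency`, `annotations`, `catalog`.
#' @export
annotated_network <- function(proteins, adjacency,
                              annotations = empty_annotations(),
                              catalog = NULL) {
  proteins <- as.character(proteins)
  if (anyDuplicated(proteins)) stop("protein identifiers must be unique")
  if (length(proteins) == 0L) stop("network must contain at least one protein")
  ord <- order(proteins)
  proteins <- proteins[ord]
  adjacency <- as.matrix(adjacency)
  if (!is.null(rownames(adjacency))) {
    if (!setequal(rownames(adjacency), proteins))
      stop("adjacency dimnames do not match the protein set")
    adjacency <- adjacency[proteins, proteins, drop = FALSE]
  } else {
    adjacency <- adjacency[ord, ord, drop = FALSE]
    dimnames(adjacency) <- list(proteins, proteins)
  }
  storage.mode(adjacency) <- "integer"
  validate_adjacency(adjacency)

  annotations <- validate_annotations(annotations, proteins)
  if (is.null(catalog)) catalog <- catalog_from_annotations(annotations)
  check_annotations_in_catalog(annotations, catalog)

  structure(list(proteins = proteins, adjacency = adjacency,
                 annotations = annotations, catalog = catalog),
            class = "annotated_network")
}

empty_annotations <- function() {
  data.frame(protein = character(), category = character(),
             value = character(), stringsAsFactors = FALSE)
}

validate_adjacency <- function(A) {
  if (nrow(A) != ncol(A)) stop("adjacency must be square")
  if (!all(A %in% c(0L, 1L))) stop("adjacency entries must be 0 or 1")
  if (!identical(A, t(A))) stop("adjacency must be symmetric")
  if (any(diag(A) != 0L)) stop("adjacency diagonal must be zero")
  invisible(A)
}

validate_annotations <- function(ann, proteins) {
  need <- c("protein", "category", "value")
  if (!all(need %in% names(ann)))
    stop("annotations need columns protein, category, value")
  ann <- data.frame(protein = as.character(ann$protein),
                    category = as.character(ann$category),
                    value = as.character(ann$value),
                    stringsAsFactors = FALSE)
  missing <- setdiff(unique(ann$protein), proteins)
  if (length(missing))
    stop("annotations reference unknown proteins: ",
         paste(utils::head(missing, 5), collapse = ", "))
  ann
}

#' Gene Ontology category catalog
#'
#' The catalog lists the annotation categories (e.g. GO aspects) and, for each,
#' the ordered domain of admissible annotation values. The domains define the
#' support of the per-module value distributions in the generative model.
#'
#' @param categories character vector of unique category identifiers.
#' @param domains named list (names = `categories`) of non-empty character
#'   vectors of unique values.
#' @return An object of class `go_catalog` with elements `categories`,
#'   `domains`.
#' @export
go_catalog <- function(categories, domains) {
  categories <- as.character(categories)
  if (anyDuplicated(categories)) stop("category identifiers must be unique")
  dom_names <- if (is.null(names(domains))) character(0) else names(domains)
  if (!identical(sort(dom_names), sort(categories)))
    stop("domains must be a named list matching categories")
  domains <- lapply(domains[categories], as.character)
  for (m in categories) {
    if (length(domains[[m]]) == 0L) stop("empty domain for category ", m)
    if (anyDuplicated(domains[[m]])) stop("duplicate values in domain of ", m)
  }
  structure(list(categories = categories, domains = domains),
            class = "go_catalog")
}

catalog_from_annotations <- function(ann) {
  if (nrow(ann) == 0L) return(go_catalog(character(), list()))
  cats <- sort(unique(ann$category))
  doms <- lapply(cats, function(m) sort(unique(ann$value[ann$category == m])))
  names(doms) <- cats
  go_catalog(cats, doms)
}

check_annotations_in_catalog <- function(ann, catalog) {
  if (nrow(ann) == 0L) return(invisible(TRUE))
  bad_cat <- setdiff(unique(ann$category), catalog$categories)
  if (length(bad_cat))
    stop("annotation categories not in catalog: ",
         paste(bad_cat, collapse = ", "))
  for (m in unique(ann$category)) {
    vals <- ann$value[ann$category == m]
    bad <- setdiff(unique(vals), catalog$domains[[m]])
    if (length(bad))
      stop("values outside dom(", m, "): ",
           paste(utils::head(bad, 5), collapse = ", "))
  }
  invisible(TRUE)
}

#' @export
print.annotated_network <- function(x, ...) {
  st <- network_stats(x)
  cat(sprintf(
    "annotated_network: %d proteins, %d edges (avg degree %.2f, CC %.3f)\n",
    st$n_nodes, st$n_edges, st$avg_degree, st$clustering))
  cat(sprintf("  annotations: %d rows over %d categories\n",
              nrow(x$annotations), length(x$catalog$categories)))
  invisible(x)
}

protein_index <- function(net, ids) {
  idx <- match(as.character(ids), net$proteins)
  if (anyNA(idx))
    stop("unknown protein(s): ",
         paste(unique(ids[is.na(idx)]), collapse = ", "))
  idx
}

#' Descriptive network statistics
#'
#' Node count N, edge count E, average degree 2E/N and mean local clustering
#' coefficient (nodes of degree < 2 contribute 0).
#'
#' @param net an [annotated_network()].
#' @return A list of class `network_stats` with `n_nodes`, `n_edges`,
#'   `avg_degree`, `clustering`.
#' @export
network_stats <- function(net) {
  A <- net$adjacency
  n <- nrow(A)
  deg <- rowSums(A)
  e <- sum(A) / 2
  cc <- vapply(seq_len(n), function(i) {
    d <- deg[i]
    if (d < 2) return(0)
    nb <- which(A[i, ] == 1L)
    sum(A[nb, nb]) / (d * (d - 1))
  }, numeric(1))
  structure(list(n_nodes = n, n_edges = as.integer(e),
                 avg_degree = 2 * e / n, clustering = mean(cc)),
            class = "network_stats")
}

#' @export
print.network_stats <- function(x, ...) {
  cat(sprintf("N = %d  E = %d  k_av = %.2f  CC = %.3f\n",
              x$n_nodes, x$n_edges, x$avg_degree, x$clustering))
  invisible(x)
}

#' Read an annotated PPI network from files
#'
#' The edge list is a two-column whitespace- or tab-separated file, one
#' undirected edge per line; lines starting with `#` are ignored. Duplicate
#' edges (in either orientation) collapse to one; self-loops are dropped with
#' a warning. The optional annotation source is either a TSV with header
#' `protein category value`, or a GAF 2.x file (`gaf = TRUE`; column 2 = DB
#' object id, column 5 = GO id, column 9 = aspect, with aspects P/F/C used as
#' the categories). Proteins present only in the annotation file become
#' isolated nodes.
#'
#' @param edge_path path to the edge-list file.
#' @param annotation_path optional path to the annotation file.
#' @param gaf logical; parse `annotation_path` as GAF 2.x.
#' @return An [annotated_network()].
#' @export
read_network <- function(edge_path, annotation_path = NULL, gaf = FALSE) {
  lines <- readLines(edge_path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]
  line_no <- which(keep)
  if (length(lines) == 0L) stop("empty edge list: ", edge_path)
  parts <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(lengths(parts) != 2L)
  if (length(bad))
    stop("malformed edge line ", line_no[bad[1]], " in ", edge_path,
         " (expected 2 columns, got ", lengths(parts)[bad[1]], ")")
  from <- vapply(parts, `[`, character(1), 1L)
  to <- vapply(parts, `[`, character(1), 2L)

  self <- from == to
  if (any(self)) {
    warning(sum(self), " self-loop(s) dropped from ", edge_path)
  }
  ann <- if (is.null(annotation_path)) empty_annotations()
         else if (gaf) read_gaf(annotation_path)
         else read_annotation_table(annotation_path)

  proteins <- sort(unique(c(from, to, ann$protein)))
  a <- match(from[!self], proteins)
  b <- match(to[!self], proteins)
  A <- matrix(0L, length(proteins), length(proteins),
              dimnames = list(proteins, proteins))
  A[cbind(a, b)] <- 1L
  A[cbind(b, a)] <- 1L
  annotated_network(proteins, A, ann)
}

read_annotation_table <- function(path) {
  ann <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character",
                           comment.char = "#", quote = "")
  validate_annotations(ann, unique(ann$protein))
}

read_gaf <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(!|$)", lines)]
  if (length(lines) == 0L) return(empty_annotations())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 9L)
  if (length(bad))
    stop("malformed GAF line ", bad[1], " in ", path,
         " (fewer than 9 columns)")
  data.frame(protein = vapply(parts, `[`, character(1), 2L),
             category = vapply(parts, `[`, character(1), 9L),
             value = vapply(parts, `[`, character(1), 5L),
             stringsAsFactors = FALSE)
}

#' Write an annotated network to disk
#'
#' Writes the edge list (TSV, two columns, no header; each undirected edge
#' once with endpoints in sorted order) and the annotation table (TSV with
#' header `protein	category	value`). `read_network()` on the outputs
#' reproduces the protein set, edge set and annotation multiset.
#'
#' @param net an [annotated_network()].
#' @param edge_path,annotation_path output file paths.
#' @return Invisibly, `c(edge_path, annotation_path)`.
#' @export
write_network <- function(net, edge_path, annotation_path = NULL) {
  A <- net$adjacency
  idx <- which(upper.tri(A) & A == 1L, arr.ind = TRUE)
  lines <- sprintf("%s\t%s", net$proteins[idx[, 1]], net$proteins[idx[, 2]])
  # isolated proteins cannot be represented in a pure edge list; they survive
  # a round trip through the annotation file only if annotated
  writeLines(lines, edge_path)
  if (!is.null(annotation_path)) {
    utils::write.table(net$annotations, annotation_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(c(edge_path, annotation_path))
}

#' Export a module-membership matrix as TSV
#'
#' Header `protein	module_1 .. module_K`, one row per protein.
#'
#' @param membership matrix with rownames = protein identifiers.
#' @param path output path.
#' @export
write_membership <- function(membership, path) {
  df <- data.frame(protein = rownames(membership), membership,
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("protein", paste0("module_", seq_len(ncol(membership))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
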