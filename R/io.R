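# Readers/writers for the plain-text formats the pipeline touches. All
# functions accept a file path or a connection, so tests can run in memory via
# textConnection(). Parsers reject structural errors rather than repairing
# them; writers emit files their own parser accepts.

.read_lines <- function(file) {
  if (is.character(file)) readLines(file, warn = FALSE) else readLines(file)
}

.write_lines <- function(lines, file) {
  if (is.character(file)) writeLines(lines, file) else writeLines(lines, file)
  invisible(NULL)
}

.num <- function(x) sprintf("%.10g", x)

#' Parse a GCT 1.2 expression file
#'
#' Strict reader for the GCT 1.2 dialect: `#1.2`, a dimensions line, a header
#' row, then one row per gene (`NAME`, `Description`, values). Declared
#' dimensions are checked against content; duplicate gene names and
#' non-numeric cells are errors naming the offending line.
#'
#' @param file Path or connection.
#' @return A [SummarizedExperiment::SummarizedExperiment] with assay `exprs`
#'   and a `Description` column in `rowData`. Sample metadata is attached
#'   separately (see [attach_design()]).
#' @export
parse_gct <- function(file) {
  lines <- .read_lines(file)
  if (length(lines) < 3) stop("GCT: fewer than 3 lines")
  if (trimws(lines[1]) != "#1.2")
    stop("GCT line 1: expected '#1.2', got '", lines[1], "'")
  dims <- strsplit(trimws(lines[2]), "\t")[[1]]
  if (length(dims) < 2 || anyNA(suppressWarnings(as.integer(dims[1:2]))))
    stop("GCT line 2: expected '<n_genes>\\t<n_samples>'")
  ng <- as.integer(dims[1]); ns <- as.integer(dims[2])
  header <- strsplit(lines[3], "\t", fixed = TRUE)[[1]]
  if (length(header) != ns + 2)
    stop("GCT line 3: header has ", length(header) - 2,
         " sample columns, declared ", ns)
  sample_ids <- trimws(header[-(1:2)])
  if (anyDuplicated(sample_ids)) stop("GCT: duplicate sample identifiers")
  body <- lines[-(1:3)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != ng)
    stop("GCT: declared ", ng, " genes, ", length(body), " present (at EOF)")
  parts <- strsplit(body, "\t", fixed = TRUE)
  genes <- character(ng); desc <- character(ng)
  values <- matrix(NA_real_, ng, ns)
  for (i in seq_len(ng)) {
    row <- parts[[i]]
    line_no <- i + 3
    if (length(row) != ns + 2)
      stop("GCT line ", line_no, ": expected ", ns + 2, " fields, got ",
           length(row))
    genes[i] <- trimws(row[1]); desc[i] <- row[2]
    v <- suppressWarnings(as.numeric(row[-(1:2)]))
    if (anyNA(v))
      stop("GCT line ", line_no, ": non-numeric expression value")
    values[i, ] <- v
  }
  if (anyDuplicated(genes))
    stop("GCT: duplicate NAME '", genes[anyDuplicated(genes)], "'")
  dimnames(values) <- list(genes, sample_ids)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = values),
    rowData = S4Vectors::DataFrame(Description = desc, row.names = genes))
}

#' Write a GCT 1.2 expression file
#'
#' @param se SummarizedExperiment (first assay is written).
#' @param file Path or connection.
#' @export
write_gct <- function(se, file) {
  x <- SummarizedExperiment::assay(se)
  desc <- rep("na", nrow(x))
  rd <- SummarizedExperiment::rowData(se)
  if ("Description" %in% colnames(rd)) desc <- as.character(rd$Description)
  lines <- c("#1.2",
             paste(nrow(x), ncol(x), sep = "\t"),
             paste(c("NAME", "Description", colnames(x)), collapse = "\t"),
             vapply(seq_len(nrow(x)), function(i)
               paste(c(rownames(x)[i], desc[i], .num(x[i, ])),
                     collapse = "\t"), ""))
  .write_lines(lines, file)
}

#' Parse a categorical CLS phenotype file
#'
#' Three-line categorical dialect: `<n> <k> 1`, `# lab1 lab2 ...`, then `n`
#' labels given either by name or by 0-based class index.
#'
#' @param file Path or connection.
#' @return Character vector of class labels with attribute `classes`.
#' @export
parse_cls <- function(file) {
  lines <- .read_lines(file)
  if (length(lines) < 3) stop("CLS: fewer than 3 lines")
  hdr <- strsplit(trimws(lines[1]), "[ \t]+")[[1]]
  if (length(hdr) < 2) stop("CLS line 1: expected '<n> <k> 1'")
  n <- as.integer(hdr[1]); k <- as.integer(hdr[2])
  cls_line <- strsplit(trimws(lines[2]), "[ \t]+")[[1]]
  if (cls_line[1] != "#") stop("CLS line 2: must start with '#'")
  classes <- cls_line[-1]
  if (length(classes) != k)
    stop("CLS: declared ", k, " classes, named ", length(classes))
  labs <- strsplit(trimws(lines[3]), "[ \t]+")[[1]]
  if (length(labs) != n)
    stop("CLS: declared ", n, " samples, found ", length(labs), " labels")
  if (all(labs %in% as.character(seq_len(k) - 1)))
    labs <- classes[as.integer(labs) + 1]
  if (!all(labs %in% classes))
    stop("CLS: label not among declared classes: ",
         paste(unique(setdiff(labs, classes)), collapse = ", "))
  structure(labs, classes = classes)
}

#' Write a categorical CLS phenotype file
#' @param labels Character vector of class labels.
#' @param file Path or connection.
#' @export
write_cls <- function(labels, file) {
  classes <- unique(labels)
  .write_lines(c(paste(length(labels), length(classes), "1"),
                 paste(c("#", classes), collapse = " "),
                 paste(labels, collapse = " ")), file)
}

#' Parse a GMT gene-set collection
#'
#' `name TAB description TAB member...` per line. Duplicate members within a
#' set are removed with a warning; empty sets and duplicate set names are
#' errors.
#'
#' @param file Path or connection.
#' @return Named list of character vectors with attribute `descriptions`.
#' @export
parse_gmt <- function(file) {
  lines <- .read_lines(file)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list(); descs <- character(0)
  for (i in seq_along(lines)) {
    parts <- trimws(strsplit(lines[i], "\t", fixed = TRUE)[[1]])
    if (length(parts) < 3)
      stop("GMT line ", i, ": set '", parts[1], "' is empty")
    name <- parts[1]
    if (name %in% names(sets)) stop("GMT: duplicate set name '", name, "'")
    members <- parts[-(1:2)]
    members <- members[nzchar(members)]
    if (!length(members)) stop("GMT line ", i, ": set '", name, "' is empty")
    if (anyDuplicated(members)) {
      warning("GMT line ", i, ": duplicate members in '", name, "' removed")
      members <- unique(members)
    }
    sets[[name]] <- members
    descs[name] <- parts[2]
  }
  structure(sets, descriptions = descs)
}

#' Write a GMT gene-set collection
#' @param sets Named list of character vectors.
#' @param file Path or connection.
#' @export
write_gmt <- function(sets, file) {
  descs <- attr(sets, "descriptions")
  if (is.null(descs)) descs <- setNames(rep("na", length(sets)), names(sets))
  .write_lines(vapply(names(sets), function(nm)
    paste(c(nm, descs[[nm]], sets[[nm]]), collapse = "\t"), ""), file)
}

#' Parse a SIF molecular-interaction file
#'
#' `nodeA TAB relation TAB nodeB [TAB nodeC ...]`: multi-target lines expand
#' to one edge per target; a single-token line declares an isolated node.
#' Duplicate edges are collapsed; self-loops are rejected.
#'
#' @param file Path or connection.
#' @return Undirected simple [igraph::igraph] with edge attribute `relation`.
#' @export
parse_sif <- function(file) {
  lines <- .read_lines(file)
  lines <- lines[nzchar(trimws(lines))]
  from <- character(0); to <- character(0); rel <- character(0)
  isolated <- character(0)
  for (i in seq_along(lines)) {
    parts <- trimws(strsplit(lines[i], "\t", fixed = TRUE)[[1]])
    parts <- parts[nzchar(parts)]
    if (length(parts) == 1) { isolated <- c(isolated, parts); next }
    if (length(parts) == 2)
      stop("SIF line ", i, ": relation without target node")
    targets <- parts[-(1:2)]
    if (parts[1] %in% targets)
      stop("SIF line ", i, ": self-loop on '", parts[1], "'")
    from <- c(from, rep(parts[1], length(targets)))
    to <- c(to, targets)
    rel <- c(rel, rep(parts[2], length(targets)))
  }
  nodes <- .id_sort(unique(c(from, to, isolated)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to, relation = rel,
               stringsAsFactors = FALSE),
    directed = FALSE, vertices = nodes)
  igraph::simplify(g, edge.attr.comb = list(relation = "first"))
}

#' Write a SIF molecular-interaction file
#' @param graph Undirected igraph; edge attribute `relation` (default "pp").
#' @param file Path or connection.
#' @export
write_sif <- function(graph, file) {
  el <- igraph::as_edgelist(graph)
  rel <- igraph::edge_attr(graph, "relation")
  if (is.null(rel)) rel <- rep("pp", nrow(el))
  # canonical edge orientation and ordering for byte-stable output
  swap <- el[, 1] > el[, 2]
  el[swap, ] <- el[swap, 2:1]
  ord <- .id_order(el[, 1], el[, 2])
  lines <- if (nrow(el)) paste(el[ord, 1], rel[ord], el[ord, 2], sep = "\t")
           else character(0)
  deg <- igraph::degree(graph)
  lines <- c(lines, .id_sort(names(deg)[deg == 0]))
  .write_lines(lines, file)
}

#' Read / write a per-sample covariate table
#'
#' Tab-separated with header `sample_id`, `value`.
#' @param file Path or connection.
#' @return data.frame with `sample_id` (character), `value` (numeric).
#' @export
read_covariate_tsv <- function(file) {
  df <- read.delim(file, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("sample_id", "value") %in% names(df)))
    stop("covariate TSV: header must contain sample_id, value")
  if (!is.numeric(df$value)) stop("covariate TSV: value column not numeric")
  df$sample_id <- trimws(as.character(df$sample_id))
  df[, c("sample_id", "value")]
}

#' @rdname read_covariate_tsv
#' @param df data.frame with `sample_id`, `value`.
#' @export
write_covariate_tsv <- function(df, file) {
  .write_tsv(df[, c("sample_id", "value")], file)
}

#' Read / write the sample design table
#'
#' Tab-separated with header `sample_id`, `subject`, `group`, `timepoint`;
#' groups must be in N1/N2/M and timepoints in T0/T1/T2.
#' @param file Path or connection.
#' @return Validated data.frame.
#' @export
read_design_tsv <- function(file) {
  df <- read.delim(file, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample_id", "subject", "group", "timepoint")
  if (!all(need %in% names(df)))
    stop("design TSV: header must contain ", paste(need, collapse = ", "))
  df <- df[, need]
  df[] <- lapply(df, function(x) trimws(as.character(x)))
  if (anyDuplicated(df$sample_id)) stop("design TSV: duplicate sample_id")
  if (!all(df$group %in% GROUPS))
    stop("design TSV: group must be one of ", paste(GROUPS, collapse = "/"))
  if (!all(df$timepoint %in% TIMEPOINTS))
    stop("design TSV: timepoint must be one of ",
         paste(TIMEPOINTS, collapse = "/"))
  df
}

#' @rdname read_design_tsv
#' @param df Design data.frame.
#' @export
write_design_tsv <- function(df, file) {
  .write_tsv(df[, c("sample_id", "subject", "group", "timepoint")], file)
}

#' Attach a sample design table to an expression matrix
#'
#' @param se SummarizedExperiment (e.g. from [parse_gct()]).
#' @param design data.frame from [read_design_tsv()]; must cover every sample.
#' @return `se` with `subject`, `group`, `timepoint` in its `colData`.
#' @export
attach_design <- function(se, design) {
  idx <- match(colnames(se), design$sample_id)
  if (anyNA(idx))
    stop("design missing samples: ",
         paste(head(colnames(se)[is.na(idx)], 5), collapse = ", "))
  cd <- design[idx, ]
  SummarizedExperiment::colData(se)$sample_id <- cd$sample_id
  SummarizedExperiment::colData(se)$subject <- cd$subject
  SummarizedExperiment::colData(se)$group <- cd$group
  SummarizedExperiment::colData(se)$timepoint <- cd$timepoint
  se
}

#' Collapse duplicate probes mapping to one gene
#'
#' For each duplicated identifier keeps the probe with the largest maximum
#' absolute deviation from its own grand mean (the most responsive probe).
#'
#' @param se SummarizedExperiment whose rownames may repeat.
#' @return SummarizedExperiment with unique rownames.
#' @export
collapse_duplicate_genes <- function(se) {
  x <- SummarizedExperiment::assay(se)
  score <- apply(x, 1, function(v) max(abs(v - mean(v))))
  keep <- unlist(lapply(split(seq_len(nrow(x)), rownames(x)),
                        function(idx) idx[which.max(score[idx])]),
                 use.names = FALSE)
  se[sort(keep), ]
}

#' Quantile-normalize an expression matrix (plumbing)
#'
#' Thin wrapper around [limma::normalizeQuantiles] for inputs that are not
#' already normalized; the pipeline otherwise assumes a pre-normalized
#' log-scale matrix.
#'
#' @param se SummarizedExperiment.
#' @return SummarizedExperiment with normalized first assay.
#' @export
quantile_normalize <- function(se) {
  x <- limma::normalizeQuantiles(SummarizedExperiment::assay(se))
  SummarizedExperiment::assay(se) <- x
  se
}

# byte-stable TSV writer: numeric columns through %.10g, no quoting
.write_tsv <- function(df, file) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]]))
      out[[j]] <- .num(out[[j]])
  }
  lines <- c(paste(names(out), collapse = "\t"),
             if (nrow(out)) do.call(paste,
               c(unname(as.list(out)), sep = "\t")) else character(0))
  .write_lines(lines, file)
}
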