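# Readers and writers for proteome annotation tables and STRING-style
# interaction edge lists.
#
# Proteome tables are TSV with header; required columns `protein_id`,
# `length_aa` and at least one of `oligomer_k` (explicit subunit number) or
# `subunit_annotation` (UniProt-style free text, parsed here). Optional
# columns: `organism`, `go_terms` (pipe-separated), `abundance`.

# Greek-prefix oligomer vocabulary used in UniProt subunit annotations.
.oligo_prefixes <- c(
  mono = 1, di = 2, tri = 3, tetra = 4, penta = 5, hexa = 6, hepta = 7,
  octa = 8, nona = 9, deca = 10, undeca = 11, dodeca = 12, trideca = 13,
  tetradeca = 14, pentadeca = 15, hexadeca = 16, heptadeca = 17,
  octadeca = 18, nonadeca = 19, icosa = 20, eicosa = 20, tetracosa = 24
)

#' Parse a UniProt-style subunit-structure annotation
#'
#' Extracts the homo-oligomer subunit number k from free-text annotations
#' such as "Homotetramer." or "Homodimer; can also form homotetramers.".
#' Recognized forms: "monomer" (k = 1), Greek-prefixed "homo<prefix>mer"
#' terms up to homotetracosamer (k = 24), and numeric "homo-N-mer".
#' Annotations mentioning only hetero-oligomers yield `is_homo = FALSE`
#' with unknown k; "homooligomer" with no number yields `is_homo = TRUE`
#' with unknown k; anything else is unknown. When several distinct homo
#' states are mentioned, the state chosen follows `policy` (default:
#' first mention, UniProt's primary description convention) and all states
#' are recorded in `ambiguity_note`.
#'
#' Unparseable text never raises an error; it simply yields unknown.
#'
#' @param text character vector of annotations (NA and "" allowed).
#' @param policy how to resolve multiple homo-oligomer states: first
#'   mention, smallest k, or largest k.
#' @return data frame with one row per input: `oligomer_k` (integer or
#'   NA), `is_homo` (logical, NA when nothing recognized), and
#'   `ambiguity_note` ("" or the comma-separated sorted k values seen).
#' @examples
#' parse_subunit_annotation("Homotetramer.")
#' parse_subunit_annotation("Homodimer; can also form homotetramers.")
#' parse_subunit_annotation("Heterodimer of subunits A and B.")
#' @export
parse_subunit_annotation <- function(text, policy = c("first", "min", "max")) {
  policy <- match.arg(policy)
  text <- as.character(text)
  num_pat <- "homo-?([0-9]{1,3})-?mers?"
  greek_pat <- paste0("homo-?(", paste(names(.oligo_prefixes), collapse = "|"),
                      ")mers?")
  mono_pat <- "(?<!homo)(?<!o)\\bmonomers?\\b"
  olig_pat <- "homo-?oligomer"
  hetero_pat <- "hetero"

  one <- function(s) {
    if (is.na(s) || !nzchar(s)) {
      return(list(k = NA_integer_, homo = NA, note = ""))
    }
    sl <- tolower(s)
    pos <- integer(0)
    kv <- integer(0)
    m <- gregexpr(greek_pat, sl, perl = TRUE)[[1]]
    if (m[1] != -1) {
      hits <- regmatches(sl, list(m))[[1]]
      pref <- sub("mers?$", "", sub("^homo-?", "", hits))
      pos <- c(pos, as.integer(m))
      kv <- c(kv, as.integer(.oligo_prefixes[pref]))
    }
    m <- gregexpr(num_pat, sl, perl = TRUE)[[1]]
    if (m[1] != -1) {
      hits <- regmatches(sl, list(m))[[1]]
      num <- as.integer(sub("-?mers?$", "", sub("^homo-?", "", hits)))
      pos <- c(pos, as.integer(m))
      kv <- c(kv, num)
    }
    m <- gregexpr(mono_pat, sl, perl = TRUE)[[1]]
    if (m[1] != -1) {
      pos <- c(pos, as.integer(m))
      kv <- c(kv, rep(1L, length(m)))
    }
    kv <- kv[kv >= 1L]
    pos <- pos[seq_along(kv)]
    if (length(kv) > 0) {
      k <- switch(policy,
                  first = kv[which.min(pos)],
                  min = min(kv),
                  max = max(kv))
      uk <- sort(unique(kv))
      note <- if (length(uk) > 1) paste(uk, collapse = ",") else ""
      return(list(k = as.integer(k), homo = TRUE, note = note))
    }
    if (grepl(olig_pat, sl, perl = TRUE)) {
      return(list(k = NA_integer_, homo = TRUE, note = "homooligomer without k"))
    }
    if (grepl(hetero_pat, sl, perl = TRUE)) {
      return(list(k = NA_integer_, homo = FALSE, note = ""))
    }
    list(k = NA_integer_, homo = NA, note = "")
  }

  parsed <- lapply(text, one)
  data.frame(
    oligomer_k = vapply(parsed, function(p) p$k, integer(1)),
    is_homo = vapply(parsed, function(p) p$homo, logical(1)),
    ambiguity_note = vapply(parsed, function(p) p$note, character(1)),
    stringsAsFactors = FALSE
  )
}

#' Read a proteome annotation table
#'
#' Reads a TSV proteome table into a protein-record data frame. When the
#' explicit `oligomer_k` column is absent, the `subunit_annotation` column
#' is parsed with [parse_subunit_annotation()]. Rows violating record
#' invariants (`length_aa` < 1 or non-numeric, explicit `oligomer_k` < 1)
#' are dropped, counted in the `n_malformed` attribute and reported with a
#' message — never fatal.
#'
#' @param path TSV file with header.
#' @param policy passed to [parse_subunit_annotation()].
#' @return data frame with columns `protein_id`, `organism`, `length_aa`,
#'   `oligomer_k`, `is_homo`, `ambiguity_note`, `go_terms`, `abundance`;
#'   attribute `n_malformed` counts dropped rows.
#' @export
read_proteome_table <- function(path, policy = "first") {
  if (!file.exists(path)) stop_format_error("file not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE, na.strings = c("NA", ""))
  for (col in c("protein_id", "length_aa")) {
    if (!col %in% names(df)) {
      stop_format_error("proteome table lacks required column '%s'", col)
    }
  }
  if (!any(c("oligomer_k", "subunit_annotation") %in% names(df))) {
    stop_format_error(
      "proteome table needs column 'oligomer_k' or 'subunit_annotation'")
  }

  n0 <- nrow(df)
  length_aa <- suppressWarnings(as.numeric(df$length_aa))
  bad <- is.na(length_aa) | length_aa < 1 | length_aa != floor(length_aa)

  if ("oligomer_k" %in% names(df)) {
    k <- suppressWarnings(as.integer(df$oligomer_k))
    # explicit 0 or negative k is malformed; absent k is legitimately unknown
    k_given <- !is.na(df$oligomer_k)
    bad <- bad | (k_given & (is.na(k) | k < 1))
    is_homo <- if ("is_homo" %in% names(df)) as.logical(df$is_homo) else
      ifelse(is.na(k), NA, TRUE)
    note <- rep("", n0)
  } else {
    parsed <- parse_subunit_annotation(df$subunit_annotation, policy = policy)
    k <- parsed$oligomer_k
    is_homo <- parsed$is_homo
    note <- parsed$ambiguity_note
  }

  out <- data.frame(
    protein_id = as.character(df$protein_id),
    organism = if ("organism" %in% names(df)) as.character(df$organism)
               else NA_character_,
    length_aa = as.integer(length_aa),
    oligomer_k = k,
    is_homo = is_homo,
    ambiguity_note = note,
    go_terms = if ("go_terms" %in% names(df)) as.character(df$go_terms)
               else NA_character_,
    abundance = if ("abundance" %in% names(df))
      suppressWarnings(as.numeric(df$abundance)) else NA_real_,
    stringsAsFactors = FALSE
  )
  bad <- bad | is.na(out$protein_id)
  out <- out[!bad, , drop = FALSE]
  rownames(out) <- NULL
  if (any(bad)) {
    message(sum(bad), " malformed row(s) dropped from ", path)
  }
  attr(out, "n_malformed") <- sum(bad)
  out
}

#' Write a proteome annotation table
#'
#' Inverse of [read_proteome_table()]: records written with this function
#' read back identically (up to the `n_malformed` attribute).
#'
#' @param records protein-record data frame.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_proteome_table <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Construct a protein-protein interaction graph
#'
#' A simple undirected graph: a character vector of node ids and a
#' two-column character matrix of edges. Edges are canonicalized so the
#' lexicographically smaller id comes first. Self-loops, duplicate edges
#' and edges with endpoints outside the node set violate the invariants
#' and raise an error.
#'
#' @param nodes character vector of protein ids (may include isolated
#'   nodes).
#' @param edges two-column matrix or data frame of id pairs.
#' @param discarded_stubs bookkeeping from the configuration-model
#'   realization, if any.
#' @return object of class `ppi_graph` with elements `nodes`, `edges`,
#'   `discarded_stubs`.
#' @export
ppi_graph <- function(nodes, edges, discarded_stubs = 0L) {
  nodes <- unique(as.character(nodes))
  edges <- as.matrix(edges)
  if (length(edges) == 0) {
    edges <- matrix(character(0), ncol = 2)
  }
  if (ncol(edges) != 2) stop_invalid_parameter("edges must have two columns")
  storage.mode(edges) <- "character"
  if (any(edges[, 1] == edges[, 2])) {
    stop_invalid_parameter("self-loops are not allowed in a ppi_graph")
  }
  a <- pmin(edges[, 1], edges[, 2])
  b <- pmax(edges[, 1], edges[, 2])
  key <- paste(a, b, sep = "\r")
  if (anyDuplicated(key)) {
    stop_invalid_parameter("duplicate edges are not allowed in a ppi_graph")
  }
  if (!all(c(a, b) %in% nodes)) {
    stop_invalid_parameter("every edge endpoint must be a node")
  }
  structure(
    list(nodes = nodes, edges = cbind(a = a, b = b),
         discarded_stubs = as.integer(discarded_stubs)),
    class = "ppi_graph"
  )
}

#' @export
print.ppi_graph <- function(x, ...) {
  cat(sprintf("ppi_graph: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  if (x$discarded_stubs > 0) {
    cat(sprintf("  (%d stubs discarded during realization)\n",
                x$discarded_stubs))
  }
  invisible(x)
}

#' Read a STRING-style interaction edge list
#'
#' Reads a TSV edge list with two protein-id columns (named like
#' `*_id_a` / `*_id_b`, or `protein1` / `protein2`, or `protein_a` /
#' `protein_b`) and an optional `score` column. Rows with score below
#' `score_min` are dropped, (a,b)/(b,a) pairs are deduplicated to one
#' undirected edge, and self-pairs are dropped with a count (attribute
#' `n_self_dropped`).
#'
#' @param path TSV file with header.
#' @param score_min minimum combined score; 0 keeps everything (no
#'   threshold is applied by default).
#' @return a [ppi_graph()].
#' @export
read_string_edges <- function(path, score_min = 0) {
  if (!file.exists(path)) stop_format_error("file not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  nm <- names(df)
  col_a <- nm[grepl("(_id_a$|^protein1$|^protein_a$)", nm)][1]
  col_b <- nm[grepl("(_id_b$|^protein2$|^protein_b$)", nm)][1]
  if (is.na(col_a) || is.na(col_b)) {
    stop_format_error(
      "edge list needs two id columns (e.g. *_id_a/*_id_b); found: %s",
      paste(nm, collapse = ", "))
  }
  if ("score" %in% nm && nrow(df) > 0) {
    sc <- suppressWarnings(as.numeric(df$score))
    df <- df[!is.na(sc) & sc >= score_min, , drop = FALSE]
  }
  a <- as.character(df[[col_a]])
  b <- as.character(df[[col_b]])
  keep <- !is.na(a) & !is.na(b) & nzchar(a) & nzchar(b)
  a <- a[keep]; b <- b[keep]
  self <- a == b
  n_self <- sum(self)
  a <- a[!self]; b <- b[!self]
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  dup <- duplicated(key)
  g <- ppi_graph(nodes = unique(c(lo, hi)),
                 edges = cbind(lo[!dup], hi[!dup]))
  attr(g, "n_self_dropped") <- n_self
  g
}

#' Write a STRING-style interaction edge list
#'
#' Writes the edges of a [ppi_graph()] in the six-column STRING-like TSV
#' schema used by the readers; mode/action columns are filled with
#' "binding"/"binding" and score with `score`.
#'
#' @param graph a `ppi_graph`.
#' @param path output TSV path.
#' @param score constant score written for every edge.
#' @return `path`, invisibly.
#' @export
write_string_edges <- function(graph, path, score = 900) {
  stopifnot(inherits(graph, "ppi_graph"))
  df <- data.frame(
    ecoli_interaction_id_a = graph$edges[, 1],
    ecoli_interaction_id_b = graph$edges[, 2],
    ecoli_interaction_mode = "binding",
    ecoli_interaction_action = "binding",
    a_is_acting = "f",
    score = score,
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
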