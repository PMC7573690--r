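# Synthetic proteomes and interaction networks.
#
# The generators emulate the statistical structure the downstream analysis
# assumes: a proteome where only a fraction of proteins carry a known
# oligomer state, even-k frequencies decaying roughly as k/2^k with odd k
# suppressed relative to neighboring even k, and a degree sequence with a
# discrete power-law tail (gamma ~ 2-3) above a cutoff k_min over a Poisson
# head. All generators are bit-reproducible under a fixed seed.

#' Parameters for synthetic proteome generation
#'
#' @param n_proteins number of proteins (>= 0).
#' @param known_fraction probability that a protein's oligomer state is
#'   annotated, in [0, 1]. Defaults to 0.2: in curated proteomes only a
#'   minority of proteins have a known oligomerization state.
#' @param k_support ordered subunit numbers with nonzero probability
#'   (default 1..12).
#' @param odd_suppression multiplier in [0, 1] applied to the model weight
#'   k/2^k of odd k > 1 (default 0.3), reproducing the observed deficit of
#'   odd-subunit complexes relative to neighboring even ones.
#' @param monomer_weight free weight for k = 1 (default 0.5, the raw k/2^k
#'   value at k = 1); monomers sit outside the even-k model fit and get
#'   their own knob.
#' @param mean_length_aa mean protein length in amino acids (default 270,
#'   bacterial; use ~360 for eukaryotes).
#' @param abundance_dispersion log-scale standard deviation of the
#'   lognormal abundance distribution (default 1.5).
#' @param organism label stored on each record.
#' @param seed integer seed or NULL.
#' @return a list of class `proteome_sim_params`.
#' @export
proteome_sim_params <- function(n_proteins,
                                known_fraction = 0.2,
                                k_support = 1:12,
                                odd_suppression = 0.3,
                                monomer_weight = 0.5,
                                mean_length_aa = 270,
                                abundance_dispersion = 1.5,
                                organism = "synthetic",
                                seed = NULL) {
  if (length(n_proteins) != 1L || !is.finite(n_proteins) || n_proteins < 0) {
    stop_invalid_parameter("n_proteins must be a single nonnegative count")
  }
  if (known_fraction < 0 || known_fraction > 1) {
    stop_invalid_parameter("known_fraction must lie in [0, 1]")
  }
  if (odd_suppression < 0 || odd_suppression > 1) {
    stop_invalid_parameter("odd_suppression must lie in [0, 1]")
  }
  if (length(k_support) == 0 || any(k_support < 1) ||
      any(diff(k_support) <= 0)) {
    stop_invalid_parameter(
      "k_support must be nonempty, strictly increasing, with min >= 1")
  }
  if (monomer_weight < 0) {
    stop_invalid_parameter("monomer_weight must be nonnegative")
  }
  if (mean_length_aa <= 0 || abundance_dispersion <= 0) {
    stop_invalid_parameter(
      "mean_length_aa and abundance_dispersion must be positive")
  }
  structure(
    list(n_proteins = as.integer(n_proteins),
         known_fraction = known_fraction,
         k_support = as.integer(k_support),
         odd_suppression = odd_suppression,
         monomer_weight = monomer_weight,
         mean_length_aa = mean_length_aa,
         abundance_dispersion = abundance_dispersion,
         organism = organism,
         seed = seed),
    class = "proteome_sim_params"
  )
}

# Normalized sampling weights over k_support: w(k) = k/2^k for even k,
# rho * k/2^k for odd k > 1, monomer_weight for k = 1.
proteome_state_weights <- function(params) {
  k <- params$k_support
  w <- k / 2^k
  odd <- k %% 2 == 1 & k > 1
  w[odd] <- w[odd] * params$odd_suppression
  w[k == 1] <- params$monomer_weight
  if (sum(w) <= 0) {
    stop_invalid_parameter("state weights sum to zero; nothing to sample")
  }
  stats::setNames(w / sum(w), as.character(k))
}

#' Generate a synthetic proteome
#'
#' Draws `n_proteins` protein records. A `known_fraction` share carry an
#' oligomer state sampled from the normalized weights of
#' [proteome_sim_params()]; the rest have unknown state. Lengths are
#' lognormal with the requested mean (sdlog 0.45, the typical spread of
#' proteome length distributions) and abundances lognormal in ppm.
#'
#' @param params a [proteome_sim_params()] object.
#' @return protein-record data frame in the [read_proteome_table()] schema.
#' @examples
#' p <- generate_proteome(proteome_sim_params(100, seed = 1))
#' table(p$oligomer_k)
#' @export
generate_proteome <- function(params) {
  stopifnot(inherits(params, "proteome_sim_params"))
  n <- params$n_proteins
  if (n == 0) {
    return(data.frame(protein_id = character(0), organism = character(0),
                      length_aa = integer(0), oligomer_k = integer(0),
                      is_homo = logical(0), ambiguity_note = character(0),
                      go_terms = character(0), abundance = numeric(0),
                      stringsAsFactors = FALSE))
  }
  set_seed_if(params$seed)
  sdlog <- 0.45
  len <- pmax(1L, as.integer(round(stats::rlnorm(
    n, meanlog = log(params$mean_length_aa) - sdlog^2 / 2, sdlog = sdlog))))
  known <- stats::runif(n) < params$known_fraction
  k <- rep(NA_integer_, n)
  if (any(known)) {
    w <- proteome_state_weights(params)
    k[known] <- sample(params$k_support, sum(known), replace = TRUE, prob = w)
  }
  abundance <- stats::rlnorm(n, meanlog = log(10),
                             sdlog = params$abundance_dispersion)
  data.frame(
    protein_id = sprintf("SYN%06d", seq_len(n)),
    organism = params$organism,
    length_aa = len,
    oligomer_k = k,
    is_homo = ifelse(is.na(k), NA, TRUE),
    ambiguity_note = "",
    go_terms = NA_character_,
    abundance = abundance,
    stringsAsFactors = FALSE
  )
}

#' Parameters for synthetic degree-sequence generation
#'
#' @param n_nodes number of nodes (>= 1).
#' @param gamma power-law tail exponent (> 1).
#' @param k_min lower cutoff of the power-law tail (integer >= 1).
#' @param head_mean mean of the Poisson head below `k_min`; 0 puts all
#'   mass in the tail.
#' @param tail_fraction expected share of nodes with degree >= `k_min`
#'   (default 0.7, matching interaction networks where most listed
#'   proteins lie above the fitted cutoff); forced to 1 when
#'   `head_mean = 0`.
#' @param k_max upper truncation of the tail (default 10000).
#' @param seed integer seed or NULL.
#' @return a list of class `network_sim_params`.
#' @export
network_sim_params <- function(n_nodes, gamma = 2.5, k_min = 5,
                               head_mean = 3, tail_fraction = 0.7,
                               k_max = 10000, seed = NULL) {
  if (length(n_nodes) != 1L || !is.finite(n_nodes) || n_nodes < 1) {
    stop_invalid_parameter("n_nodes must be a positive count")
  }
  if (gamma <= 1) stop_invalid_parameter("gamma must exceed 1")
  if (k_min < 1 || k_min != floor(k_min)) {
    stop_invalid_parameter("k_min must be a positive integer")
  }
  if (head_mean < 0) stop_invalid_parameter("head_mean must be nonnegative")
  if (tail_fraction < 0 || tail_fraction > 1) {
    stop_invalid_parameter("tail_fraction must lie in [0, 1]")
  }
  if (k_max < k_min) stop_invalid_parameter("k_max must be >= k_min")
  if (head_mean == 0) tail_fraction <- 1
  structure(
    list(n_nodes = as.integer(n_nodes), gamma = gamma,
         k_min = as.integer(k_min), head_mean = head_mean,
         tail_fraction = tail_fraction, k_max = as.integer(k_max),
         seed = seed),
    class = "network_sim_params"
  )
}

# Draw m values from the discrete power law p(k) ~ k^-gamma on
# k_min..k_max by inverse-CDF table sampling.
sample_plaw_tail <- function(m, gamma, k_min, k_max) {
  if (m == 0) return(integer(0))
  kk <- seq.int(k_min, k_max)
  sample(kk, m, replace = TRUE, prob = kk^(-gamma))
}

#' Generate a degree sequence with a power-law tail
#'
#' Each node lands in the tail with probability `tail_fraction` and draws
#' its degree from the discrete power law `p(k) ~ k^-gamma` truncated to
#' `[k_min, k_max]`; otherwise it draws from a Poisson(`head_mean`)
#' conditioned on being below `k_min`. The degree sum is forced even by
#' incrementing the first entry when needed (so the sequence is always
#' realizable as a graph).
#'
#' @param params a [network_sim_params()] object.
#' @return integer vector of node degrees.
#' @examples
#' d <- generate_degree_sequence(network_sim_params(1000, seed = 1))
#' @export
generate_degree_sequence <- function(params) {
  stopifnot(inherits(params, "network_sim_params"))
  set_seed_if(params$seed)
  n <- params$n_nodes
  in_tail <- stats::runif(n) < params$tail_fraction
  deg <- integer(n)
  deg[in_tail] <- sample_plaw_tail(sum(in_tail), params$gamma,
                                   params$k_min, params$k_max)
  n_head <- sum(!in_tail)
  if (n_head > 0) {
    if (params$k_min == 1L) {
      deg[!in_tail] <- 0L
    } else {
      h <- stats::rpois(n_head, params$head_mean)
      while (any(h >= params$k_min)) {
        bad <- h >= params$k_min
        h[bad] <- stats::rpois(sum(bad), params$head_mean)
      }
      deg[!in_tail] <- h
    }
  }
  if (sum(deg) %% 2 == 1) deg[1] <- deg[1] + 1L
  deg
}

#' Realize a degree sequence as a simple graph
#'
#' Configuration-model stub matching with rejection: stubs are shuffled
#' and paired; pairs forming self-loops or duplicate edges are rejected
#' and their stubs returned to the pool for another pass. After
#' `max_attempt_factor * E` pairing attempts any remaining stubs are
#' discarded with a warning, and the count is reported on the graph, so
#' realized degrees match the request within the discard count.
#'
#' @param degrees integer degree vector with even sum; names, if present,
#'   become node ids (default `N000001`, ...).
#' @param seed integer seed or NULL.
#' @param max_attempt_factor attempt budget per edge.
#' @return a [ppi_graph()] whose `discarded_stubs` element counts stubs
#'   that could not be legally paired.
#' @examples
#' realize_edges(c(2, 2, 2), seed = 1)  # the triangle
#' @export
realize_edges <- function(degrees, seed = NULL, max_attempt_factor = 100) {
  if (length(degrees) == 0) {
    stop_invalid_parameter("degrees must be nonempty")
  }
  if (any(!is.finite(degrees)) || any(degrees < 0) ||
      any(degrees != floor(degrees))) {
    stop_invalid_parameter("degrees must be nonnegative integers")
  }
  if (sum(degrees) %% 2 == 1) {
    stop_invalid_parameter("degree sum must be even")
  }
  set_seed_if(seed)
  ids <- names(degrees) %||% sprintf("N%06d", seq_along(degrees))
  stubs <- rep.int(seq_along(degrees), degrees)
  n_edges_target <- length(stubs) / 2
  max_attempts <- max_attempt_factor * max(1, n_edges_target)

  edge_a <- integer(0)
  edge_b <- integer(0)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  attempts <- 0
  pool <- stubs
  while (length(pool) >= 2 && attempts < max_attempts) {
    pool <- sample(pool)
    half <- length(pool) %/% 2
    a <- pool[seq_len(half)]
    b <- pool[half + seq_len(half)]
    lo <- pmin(a, b)
    hi <- pmax(a, b)
    key <- paste(lo, hi, sep = "-")
    legal <- lo != hi & !duplicated(key) &
      !vapply(key, exists, logical(1), envir = seen, inherits = FALSE)
    for (kk in key[legal]) assign(kk, TRUE, envir = seen)
    edge_a <- c(edge_a, lo[legal])
    edge_b <- c(edge_b, hi[legal])
    attempts <- attempts + half
    leftover <- c(a[!legal], b[!legal])
    if (length(pool) %% 2 == 1) leftover <- c(leftover, pool[length(pool)])
    if (length(leftover) == length(pool)) attempts <- attempts + half
    pool <- leftover
  }
  discarded <- length(pool)
  if (discarded > 0) {
    warning(sprintf("realize_edges: %d stubs could not be paired and were discarded",
                    discarded))
  }
  ppi_graph(nodes = ids,
            edges = cbind(ids[edge_a], ids[edge_b]),
            discarded_stubs = discarded)
}

#' Assign category labels to protein records
#'
#' Samples one GO-like label per record with probabilities proportional to
#' `category_weights`, so label proportions converge to the normalized
#' weights. Labels are written into the `go_terms` column (pipe-separated
#' schema; a single label here).
#'
#' @param records protein-record data frame.
#' @param category_weights named nonnegative weights, not all zero.
#' @param seed integer seed or NULL.
#' @return `records` with `go_terms` filled in.
#' @export
assign_categories <- function(records, category_weights, seed = NULL) {
  if (length(category_weights) == 0 || is.null(names(category_weights))) {
    stop_invalid_parameter("category_weights must be a nonempty named vector")
  }
  if (any(category_weights < 0) || sum(category_weights) <= 0) {
    stop_invalid_parameter(
      "category_weights must be nonnegative and not all zero")
  }
  set_seed_if(seed)
  n <- nrow(records)
  if (n > 0) {
    records$go_terms <- sample(names(category_weights), n, replace = TRUE,
                               prob = category_weights)
  }
  records
}

#' Write a simulated dataset with a JSON parameter sidecar
#'
#' Saves a proteome table and/or edge list in the package's TSV schemas
#' and echoes the generating parameters (including seeds) into
#' `<stem>.params.json` so runs are reproducible from the sidecar alone.
#'
#' @param path_stem output path without extension.
#' @param records optional protein-record data frame.
#' @param graph optional `ppi_graph`.
#' @param params list of parameter objects to echo.
#' @return character vector of files written, invisibly.
#' @export
write_simulation <- function(path_stem, records = NULL, graph = NULL,
                             params = list()) {
  written <- character(0)
  if (!is.null(records)) {
    f <- paste0(path_stem, ".proteome.tsv")
    write_proteome_table(records, f)
    written <- c(written, f)
  }
  if (!is.null(graph)) {
    f <- paste0(path_stem, ".edges.tsv")
    write_string_edges(graph, f)
    written <- c(written, f)
  }
  sidecar <- paste0(path_stem, ".params.json")
  jsonlite::write_json(lapply(params, unclass), sidecar, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  written <- c(written, sidecar)
  invisible(written)
}
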