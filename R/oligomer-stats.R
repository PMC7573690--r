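# Homo-oligomer frequency distributions.
#
# f_s(k) = N_k / N_T: the fraction of known homo-oligomeric proteins with
# exactly k identical subunits. The default denominator N_T counts every
# protein with a known oligomer state (monomers included); the even-only
# model fits can renormalize over the parity subset instead, since
# published analyses are ambiguous about which denominator small-n
# power-law fits used — both modes are exposed.

#' Homo-oligomer frequency distribution
#'
#' Filters records to known homo-oligomer states (`is_homo` and a present
#' `oligomer_k`), groups them by subunit number k, and computes
#' `f_s(k) = N_k / N_T`. States above `k_max` are pooled into an overflow
#' bin (named `"overflow"`) that counts toward the denominator but is
#' excluded from fits and plots. With `weighting = "abundance"`, per-k
#' abundance sums replace protein counts (records with missing abundance
#' are dropped first).
#'
#' @param records protein-record data frame ([read_proteome_table()]
#'   schema).
#' @param parity restrict the numerator to `"all"`, `"even"` or `"odd"` k.
#' @param denominator `"all-known"` divides by every known state
#'   (regardless of parity); `"parity-subset"` renormalizes within the
#'   selected parity.
#' @param weighting `"count"` (proteins) or `"abundance"`.
#' @param k_max states above this are pooled into the overflow bin.
#' @param label distribution label (defaults to the records' organism).
#' @return object of class `oligomer_distribution`: `label`, `parity`,
#'   `denominator`, `weighting`, `counts` (named by k, possibly with an
#'   `overflow` element), `total`, `freqs`.
#' @examples
#' rec <- data.frame(protein_id = letters[1:10],
#'                   oligomer_k = c(1,1,1,1, 2,2,2, 4,4, 6),
#'                   is_homo = TRUE)
#' oligomer_frequency(rec)$freqs
#' @export
oligomer_frequency <- function(records,
                               parity = c("all", "even", "odd"),
                               denominator = c("all-known", "parity-subset"),
                               weighting = c("count", "abundance"),
                               k_max = 24,
                               label = NULL) {
  parity <- match.arg(parity)
  denominator <- match.arg(denominator)
  weighting <- match.arg(weighting)

  known <- !is.na(records$oligomer_k) & records$oligomer_k >= 1
  if ("is_homo" %in% names(records)) {
    known <- known & !isFALSE_vec(records$is_homo)
  }
  rec <- records[known, , drop = FALSE]
  if (weighting == "abundance") {
    if (!"abundance" %in% names(rec)) {
      stop_invalid_parameter("abundance weighting needs an abundance column")
    }
    rec <- rec[!is.na(rec$abundance), , drop = FALSE]
  }
  if (nrow(rec) == 0) {
    stop_empty_input("no records with a known homo-oligomer state")
  }

  k <- rec$oligomer_k
  wgt <- if (weighting == "count") rep(1, nrow(rec)) else rec$abundance
  over <- k > k_max
  k_chr <- ifelse(over, "overflow", as.character(k))
  counts_all <- tapply(wgt, k_chr, sum)
  counts_all <- counts_all[order(suppressWarnings(as.numeric(names(counts_all))),
                                 na.last = TRUE)]

  keep_parity <- function(nms) {
    kk <- suppressWarnings(as.numeric(nms))
    switch(parity,
           all = rep(TRUE, length(nms)),
           even = !is.na(kk) & kk %% 2 == 0,
           odd = !is.na(kk) & kk %% 2 == 1)
  }
  sel <- keep_parity(names(counts_all))
  if (parity != "all") sel <- sel & names(counts_all) != "overflow"
  counts <- counts_all[sel]
  if (length(counts) == 0) {
    stop_empty_input("no records in the requested parity subset")
  }
  total <- if (denominator == "all-known") sum(counts_all) else sum(counts)
  freqs <- counts / total

  structure(
    list(label = label %||% first_non_na(records$organism) %||% "proteome",
         parity = parity, denominator = denominator, weighting = weighting,
         counts = drop_names_array(counts), total = unname(total),
         freqs = drop_names_array(freqs)),
    class = "oligomer_distribution"
  )
}

# tapply returns 1-d arrays; flatten to plain named vectors
drop_names_array <- function(x) stats::setNames(as.vector(x), names(x))

isFALSE_vec <- function(x) !is.na(x) & !x

first_non_na <- function(x) {
  if (is.null(x)) return(NULL)
  x <- x[!is.na(x)]
  if (length(x) == 0) NULL else x[1]
}

#' @export
print.oligomer_distribution <- function(x, digits = 4, ...) {
  cat(sprintf("Homo-oligomer distribution '%s' (parity=%s, denominator=%s, weighting=%s)\n",
              x$label, x$parity, x$denominator, x$weighting))
  cat(sprintf("  total weight in denominator: %s\n", format(x$total)))
  print(round(rbind(count = x$counts, freq = x$freqs), digits))
  invisible(x)
}

#' @export
as.data.frame.oligomer_distribution <- function(x, ...) {
  data.frame(label = x$label,
             k = suppressWarnings(as.numeric(names(x$freqs))),
             count = unname(x$counts),
             freq = unname(x$freqs),
             stringsAsFactors = FALSE)
}

#' @export
plot.oligomer_distribution <- function(x, ...) {
  df <- as.data.frame(x)
  df <- df[is.finite(df$k), , drop = FALSE]
  graphics::barplot(df$freq, names.arg = df$k, xlab = "subunit number k",
                    ylab = expression(f[s](k)), main = x$label, ...)
  invisible(x)
}

#' Category-stratified homo-oligomer distribution
#'
#' Restricts the records to those carrying a given GO-like label in their
#' pipe-separated `go_terms` field, then computes [oligomer_frequency()]
#' within the category (the denominator is the known homo-oligomers of the
#' category).
#'
#' @param records protein-record data frame.
#' @param category_label label to match.
#' @param ... passed on to [oligomer_frequency()].
#' @return an `oligomer_distribution` labelled by the category.
#' @export
stratified_frequency <- function(records, category_label, ...) {
  if (!"go_terms" %in% names(records)) {
    stop_empty_input("records carry no go_terms column")
  }
  terms <- strsplit(ifelse(is.na(records$go_terms), "", records$go_terms),
                    "|", fixed = TRUE)
  hit <- vapply(terms, function(t) category_label %in% t, logical(1))
  if (!any(hit)) {
    stop_empty_input("no records carry category '%s'", category_label)
  }
  oligomer_frequency(records[hit, , drop = FALSE], ...,
                     label = category_label)
}

#' Average a set of distributions across organisms
#'
#' Per-k arithmetic mean and population standard deviation of `f_s(k)`
#' over several organisms' distributions; a k absent from a distribution
#' contributes frequency 0 there.
#'
#' @param distributions list of `oligomer_distribution` objects sharing
#'   parity and weighting settings.
#' @return object of class `average_distribution`: `mean_freqs`,
#'   `std_freqs` (named by k), `n_organisms`, `labels`.
#' @export
average_across <- function(distributions) {
  if (length(distributions) == 0) {
    stop_empty_input("no distributions to average")
  }
  ok <- vapply(distributions, inherits, logical(1), "oligomer_distribution")
  if (!all(ok)) {
    stop_invalid_parameter("all elements must be oligomer_distribution objects")
  }
  par <- unique(vapply(distributions, `[[`, character(1), "parity"))
  wgt <- unique(vapply(distributions, `[[`, character(1), "weighting"))
  if (length(par) > 1 || length(wgt) > 1) {
    stop_invalid_parameter(
      "distributions mix parity or weighting settings (%s; %s)",
      paste(par, collapse = "/"), paste(wgt, collapse = "/"))
  }
  all_k <- sort(unique(unlist(lapply(distributions,
                                     function(d) names(d$freqs)))))
  num_order <- order(suppressWarnings(as.numeric(all_k)), na.last = TRUE)
  all_k <- all_k[num_order]
  mat <- vapply(distributions, function(d) {
    f <- stats::setNames(rep(0, length(all_k)), all_k)
    f[names(d$freqs)] <- d$freqs
    f
  }, numeric(length(all_k)))
  mat <- matrix(mat, nrow = length(all_k),
                dimnames = list(all_k, NULL))
  m <- rowMeans(mat)
  s <- sqrt(rowMeans((mat - m)^2))  # population sd over organisms
  structure(
    list(mean_freqs = m, std_freqs = s,
         n_organisms = length(distributions),
         labels = vapply(distributions, `[[`, character(1), "label")),
    class = "average_distribution"
  )
}

#' @export
print.average_distribution <- function(x, digits = 4, ...) {
  cat(sprintf("Average homo-oligomer distribution over %d organisms\n",
              x$n_organisms))
  print(round(rbind(mean = x$mean_freqs, std = x$std_freqs), digits))
  invisible(x)
}

#' Serialize a distribution to JSON and tidy TSV
#'
#' Writes `<stem>.json` (label, parity, weighting, counts, freqs) and
#' `<stem>.tsv` (label, k, count, freq).
#'
#' @param x an `oligomer_distribution`.
#' @param path_stem output path without extension.
#' @return files written, invisibly.
#' @export
write_distribution <- function(x, path_stem) {
  stopifnot(inherits(x, "oligomer_distribution"))
  jf <- paste0(path_stem, ".json")
  jsonlite::write_json(
    list(label = x$label, parity = x$parity, denominator = x$denominator,
         weighting = x$weighting, total = x$total,
         counts = as.list(x$counts), freqs = as.list(x$freqs)),
    jf, auto_unbox = TRUE, digits = NA)
  tf <- paste0(path_stem, ".tsv")
  utils::write.table(as.data.frame(x), tf, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(jf, tf))
}
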