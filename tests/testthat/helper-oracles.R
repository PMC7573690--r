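# Independent brute-force oracles and tiny fixture builders, kept free of
# the package internals they check.

# Necklace count by explicit rotation-orbit enumeration of all 2^k binary
# strings.
brute_necklace <- function(k) {
  strings <- expand.grid(rep(list(0:1), k))
  canon <- apply(strings, 1, function(s) {
    rots <- vapply(seq_len(k), function(r) {
      paste(c(s[r:k], s[seq_len(r - 1)])[seq_len(k)], collapse = "")
    }, character(1))
    min(rots)
  })
  length(unique(canon))
}

# Euler totient by direct gcd counting.
brute_totient <- function(d) {
  sum(vapply(seq_len(d), function(i) gcd2(i, d) == 1, logical(1)))
}

gcd2 <- function(a, b) {
  while (b != 0) {
    t <- b; b <- a %% b; a <- t
  }
  a
}

# Hurwitz zeta by long direct summation with an integral tail bound --
# independent of the package's Euler-Maclaurin implementation.
brute_hurwitz <- function(s, a, terms = 200000L) {
  j <- seq.int(a, a + terms)
  sum(j^(-s)) + (a + terms + 1)^(1 - s) / (s - 1)
}

# Grid-search argmax of the discrete power-law likelihood, the oracle for
# mle_gamma. Step 1e-4 over (1, 6].
grid_mle_gamma <- function(values, k_min, step = 1e-4) {
  gs <- seq(1 + step, 6, by = step)
  n <- length(values)
  sumlog <- sum(log(values))
  j <- seq.int(k_min, k_min + 3000)
  logz <- vapply(gs, function(g) {
    log(sum(j^(-g)) + (k_min + 3001)^(1 - g) / (g - 1))
  }, numeric(1))
  ll <- -n * logz - gs * sumlog
  gs[which.max(ll)]
}

# Minimal protein-record data frame with known homo-oligomer states.
make_records <- function(k, go = NA_character_, abundance = NA_real_,
                         organism = "testorg") {
  n <- length(k)
  data.frame(
    protein_id = sprintf("T%04d", seq_len(n)),
    organism = organism,
    length_aa = rep(300L, n),
    oligomer_k = as.integer(k),
    is_homo = ifelse(is.na(k), NA, TRUE),
    ambiguity_note = "",
    go_terms = rep_len(go, n),
    abundance = rep_len(abundance, n),
    stringsAsFactors = FALSE
  )
}

# Total-variation distance between a named empirical frequency vector and
# a named model probability vector.
tv_distance <- function(emp, model) {
  keys <- union(names(emp), names(model))
  e <- stats::setNames(rep(0, length(keys)), keys)
  m <- e
  e[names(emp)] <- emp
  m[names(model)] <- model
  sum(abs(e - m)) / 2
}
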