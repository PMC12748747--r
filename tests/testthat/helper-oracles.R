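# Independent oracles and fixture builders used across the test files.

# Infix (semi-global) edit distance of `pattern` against any substring of
# `subject`, by a row-vectorised dynamic program (free start/end in the
# subject). Independent of the package's C++ kernel: different formulation
# (g[c] = cur[c] - c trick for the within-row insertion recurrence).
infix_edit_oracle <- function(pattern, subject) {
  p <- strsplit(pattern, "")[[1]]
  s <- strsplit(subject, "")[[1]]
  m <- length(p); n <- length(s)
  if (n == 0L) return(m)
  prev <- rep(0L, n + 1L)
  for (r in seq_len(m)) {
    sub <- prev[1:n] + (p[r] != s)
    del <- prev[2:(n + 1L)] + 1L
    tmin <- pmin(sub, del)
    g <- cummin(c(r, tmin - seq_len(n)))
    prev <- c(r, g[-1L] + seq_len(n))
  }
  min(prev)
}

# Oracle reimplementation of the junction-call decision rule on top of
# infix_edit_oracle, for agreement checks against call_junction().
call_junction_oracle <- function(insert, strand, products, max_edit = 1L) {
  tab <- strand_products(products, strand)
  d <- vapply(tab$junction, infix_edit_oracle, integer(1), subject = insert,
              USE.NAMES = FALSE)
  dmin <- min(d)
  if (dmin > max_edit) return(list(label = "unclassified",
                                   edit_distance = NA_integer_))
  winners <- tab$label[d == dmin]
  if (length(winners) == 1L)
    return(list(label = winners, edit_distance = dmin))
  keep <- products$degenerate_pairs$strand == strand
  deg <- products$degenerate_pairs[keep]
  prs <- utils::combn(winners, 2L)
  all_deg <- all(apply(prs, 2L, function(pr)
    any((deg$label1 == pr[1L] & deg$label2 == pr[2L]) |
          (deg$label1 == pr[2L] & deg$label2 == pr[1L]))))
  if (!all_deg) return(list(label = "unclassified",
                            edit_distance = NA_integer_))
  list(label = paste(sort(unique(winners)), collapse = "="),
       edit_distance = dmin)
}

# apply k random edits (substitution / insertion / deletion) to a sequence
random_edits <- function(seq, k) {
  ch <- strsplit(seq, "")[[1]]
  for (i in seq_len(k)) {
    op <- sample(c("sub", "ins", "del"), 1L)
    pos <- sample(length(ch), 1L)
    if (op == "sub") ch[pos] <- sample(setdiff(c("A", "C", "G", "T"), ch[pos]), 1L)
    else if (op == "ins") ch <- append(ch, sample(c("A", "C", "G", "T"), 1L), pos)
    else if (length(ch) > 1L) ch <- ch[-pos]
  }
  paste(ch, collapse = "")
}

# uniform random DNA strings (tests shadow the package-internal helper)
rand_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

# small simulated library used by several files
make_library <- function(substrate = "gt5",
                         kinetics = kinetics_model(),
                         n = 300L, harvest = 10, oversampling = 20,
                         error_rate = 0, seed = 42L,
                         insertions = character()) {
  spec <- example_substrate(substrate)
  prod <- enumerate_expected_products(spec, insertions)
  states <- simulate_repair(spec, kinetics, n, harvest, seed = seed)
  lib <- synthesize_reads(states, spec, prod, oversampling_mean = oversampling,
                          error_rate = error_rate, seed = seed + 1L)
  list(spec = spec, prod = prod, states = states, lib = lib)
}
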