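# Independent oracles used to freeze expected values. These deliberately
# re-derive results with naive loops and textbook formulas, sharing no code
# with the implementation paths they check.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# brute-force indel classifier: enumerate every candidate repeat unit and
# copy count explicitly and check adjacency character by character
oracle_classify <- function(ref, alt, left_context, right_context) {
  s <- if (nchar(alt) > nchar(ref)) {
    substring(alt, nchar(ref) + 1)
  } else {
    substring(ref, nchar(alt) + 1)
  }
  n <- nchar(s)
  if (n == 1) return("single_base_pair")
  for (ul in 1:n) {
    for (copies in 1:n) {
      if (ul * copies != n) next
      u <- substring(s, 1, ul)
      built <- ""
      for (i in seq_len(copies)) built <- paste0(built, u)
      if (built != s) next
      right_ok <- nchar(right_context) >= ul &&
        substring(right_context, 1, ul) == u
      left_ok <- nchar(left_context) >= ul &&
        substring(left_context, nchar(left_context) - ul + 1,
                  nchar(left_context)) == u
      if (right_ok || left_ok) return("repeat_expansion")
    }
  }
  "other"
}

# naive motif scan: test every offset with a character loop
oracle_scan <- function(window, motif) {
  k <- nchar(motif)
  hits <- integer(0)
  if (nchar(window) < k) return(hits)
  for (o in 0:(nchar(window) - k)) {
    if (substring(window, o + 1, o + k) == motif) hits <- c(hits, o)
  }
  hits
}

# scan both windows independently, offset-normalize the mutant side, and
# set-subtract — the reference diffing procedure
oracle_diff <- function(ref_window, mut_window, motifs, anchor_off,
                        net_change) {
  out <- list()
  for (i in seq_len(nrow(motifs))) {
    m <- motifs$motif[i]
    ref_hits <- oracle_scan(ref_window, m)
    mut_hits <- oracle_scan(mut_window, m)
    mapped <- ifelse(mut_hits > anchor_off, mut_hits - net_change, mut_hits)
    for (o in ref_hits) {
      if (!(o %in% mapped)) {
        out[[length(out) + 1]] <- data.frame(
          mirna = motifs$mirna[i], seed_type = motifs$seed_type[i],
          status = "disrupted", site_offset = o)
      }
    }
    for (j in seq_along(mut_hits)) {
      if (!(mapped[j] %in% ref_hits)) {
        out[[length(out) + 1]] <- data.frame(
          mirna = motifs$mirna[i], seed_type = motifs$seed_type[i],
          status = "created", site_offset = mapped[j])
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(mirna = character(), seed_type = character(),
                      status = character(), site_offset = integer()))
  }
  do.call(rbind, out)
}

# textbook Welch two-sample statistic
oracle_welch <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sx2 <- sum((x - mean(x))^2) / (nx - 1)
  sy2 <- sum((y - mean(y))^2) / (ny - 1)
  se2 <- sx2 / nx + sy2 / ny
  t_stat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((sx2 / nx)^2 / (nx - 1) + (sy2 / ny)^2 / (ny - 1))
  p <- 2 * pt(-abs(t_stat), df)
  list(t = t_stat, df = df, p = p)
}

# grid-search maximum-likelihood haplotype frequencies (allele frequencies
# fixed at their observed values, p11 swept on a fine grid)
oracle_em_grid <- function(ga, gb, step = 1e-4) {
  keep <- !is.na(ga) & !is.na(gb)
  ga <- ga[keep]; gb <- gb[keep]
  fa <- mean(ga) / 2; fb <- mean(gb) / 2
  lo <- max(0, fa + fb - 1); hi <- min(fa, fb)
  grid <- seq(lo, hi, by = step)
  cnt <- table(factor(ga, 0:2), factor(gb, 0:2))
  best <- NULL; best_ll <- -Inf
  for (p11 in grid) {
    p10 <- fa - p11; p01 <- fb - p11; p00 <- 1 - fa - fb + p11
    h <- pmax(c(p11, p10, p01, p00), 1e-12)
    pg <- matrix(c(
      h[4]^2,          2 * h[3] * h[4],                h[3]^2,
      2 * h[2] * h[4], 2 * h[1] * h[4] + 2 * h[2] * h[3], 2 * h[1] * h[3],
      h[2]^2,          2 * h[1] * h[2],                h[1]^2
    ), 3, 3, byrow = TRUE)
    ll <- sum(cnt * log(pg))
    if (ll > best_ll) {
      best_ll <- ll
      best <- c(p11 = p11, p10 = p10, p01 = p01, p00 = p00)
    }
  }
  best
}

# small complete-study fixture shared across tests (kept modest for speed)
tiny_config <- function(seed = 11, ...) {
  generator_config(rng_seed = seed, n_mirnas = 12L, n_utrs = 8L,
                   utr_length_range = c(400L, 700L), ...)
}
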