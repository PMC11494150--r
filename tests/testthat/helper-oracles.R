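# Independent oracles used across the suite. These deliberately re-derive
# quantities by brute force / second implementations and must stay
# independent of the package's code paths.

# textbook step-up Benjamini-Hochberg
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  adj <- pmin(rev(cummin(rev(ranked))), 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# upper-tail hypergeometric mass by direct combinatorial enumeration
brute_hyper <- function(k, K, n, N) {
  js <- seq(k, min(K, n))
  if (k > min(K, n)) return(0)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# scalar re-implementation of the inheritance-mode rule table, written as
# the Methods predicates read, evaluated with explicit if/else precedence
mode_oracle <- function(f1_vs_p1, f1_vs_p2, f1_vs_mpv, p1_vs_p2) {
  if (f1_vs_mpv == "equal") return("additive")
  if (f1_vs_p1 == "higher" && f1_vs_p2 == "higher") return("overdominant")
  if (f1_vs_p1 == "lower" && f1_vs_p2 == "lower") return("underdominant")
  if ((f1_vs_p1 == "equal" && p1_vs_p2 == "higher") ||
      (f1_vs_p2 == "equal" && p1_vs_p2 == "lower")) return("high_dominance")
  if ((f1_vs_p1 == "equal" && p1_vs_p2 == "lower") ||
      (f1_vs_p2 == "equal" && p1_vs_p2 == "higher")) return("low_dominance")
  "other"
}

# hand PAV truth table straight from the presence/absence definitions
pav_oracle <- function(f1, p1, p2) {
  if (p1 && p2 && !f1) return("I")
  if (xor(p1, p2) && !f1) return("II")
  if (f1 && !p1 && !p2) return("III")
  if (f1 && xor(p1, p2)) return("IV")
  if (f1 && p1 && p2) return("V")
  NA_character_
}

# small hand-built expression set: 2 genes x (1 trio x 2 roles used fully)
toy_es <- function(counts = NULL) {
  sheet <- data.frame(
    sample_id = c("H_WW_1", "H_WW_2", "H_WW_3",
                  "P1_WW_1", "P1_WW_2", "P1_WW_3",
                  "P2_WW_1", "P2_WW_2", "P2_WW_3"),
    trio_id = "T1",
    role = rep(c("hybrid", "parent1", "parent2"), each = 3),
    condition = "WW",
    replicate = rep(1:3, 3),
    stringsAsFactors = FALSE)
  if (is.null(counts)) {
    set.seed(42)
    counts <- matrix(rpois(5 * 9, 50), 5, 9,
                     dimnames = list(paste0("g", 1:5), sheet$sample_id))
  }
  trio_expression_set(counts, sheet)
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

tri_states <- c("higher", "equal", "lower")
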