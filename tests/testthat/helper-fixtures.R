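# small deterministic fixtures shared across test files

toy_counts <- function() {
  tibble::tibble(
    gene_id = c("g1", "g2", "g3"),
    WT_UT_1 = c(10L, 100L, 0L), WT_UT_2 = c(12L, 90L, 0L),
    WT_IR_1 = c(50L, 95L, 0L), WT_IR_2 = c(55L, 105L, 0L)
  )
}

toy_design <- function() {
  tibble::tibble(
    sample = c("WT_UT_1", "WT_UT_2", "WT_IR_1", "WT_IR_2"),
    genotype = "WT",
    treatment = c("UT", "UT", "IR", "IR"),
    replicate = c(1L, 2L, 1L, 2L)
  )
}

toy_genes <- function() {
  parse_gene_models(c(
    "ga\tGenA\tchr1\t1000\t2000\t+",
    "gb\tGenB\tchr1\t5000\t9000\t-",
    "gc\tGenC\tchr2\t100\t400\t+"
  ))
}

# brute-force two-sided Fisher oracle: enumerate tables with fixed margins
# using exact choose() arithmetic (doubles are exact here for margins <= 30)
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  if (n == 0) return(1)
  supp <- max(0, r1 + c1 - n):min(r1, c1)
  pr <- choose(r1, supp) * choose(n - r1, c1 - supp) / choose(n, c1)
  p_obs <- pr[supp == a]
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}
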