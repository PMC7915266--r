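# In-code fixtures: small clonotype tables with sensible defaults, and a
# random-table generator for property-style tests.

clono_fixture <- function(cdr3b, copies = 1L, donor_id = "d1",
                          cohort = "auto", antigen = "IMN",
                          trav = "TRAV12-2", traj = "TRAJ27",
                          trbv = "TRBV7-9", trbd = "TRBD1*01",
                          trbj = "TRBJ2-1", cdr3a = "CAVRDNYQLIF") {
  tibble::tibble(
    donor_id = donor_id, cohort = cohort, antigen = antigen,
    trav = trav, traj = traj, trbv = trbv, trbd = trbd, trbj = trbj,
    cdr3a = cdr3a, cdr3b = cdr3b, copies = as.integer(copies)
  )
}

random_cdr3 <- function(n, min_len = 8, max_len = 20) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  vapply(seq_len(n), function(i) {
    len <- if (min_len == max_len) min_len else sample(min_len:max_len, 1)
    paste0("C", paste(sample(aa, len - 2, replace = TRUE), collapse = ""), "F")
  }, character(1))
}

random_clonotypes <- function(n, donors = c("d1", "d2"), cohort = "auto",
                              max_copies = 5) {
  clono_fixture(
    cdr3b = random_cdr3(n),
    cdr3a = random_cdr3(n),
    copies = sample(1:max_copies, n, replace = TRUE),
    donor_id = sample(donors, n, replace = TRUE),
    cohort = cohort,
    trbv = sample(gene_catalogue("TRBV"), n, replace = TRUE),
    trbj = sample(gene_catalogue("TRBJ"), n, replace = TRUE),
    trav = sample(gene_catalogue("TRAV"), n, replace = TRUE),
    traj = sample(gene_catalogue("TRAJ"), n, replace = TRUE)
  )
}
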