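stack_conditions <- function(std, ecd) {
  std$condition <- "STD"; ecd$condition <- "ECD"
  rbind(std, ecd)
}

toy_join <- function() {
  # 4 genes; gene g1 has two transcript series (many-to-one map)
  map <- data.frame(series_id = c("t1a", "t1b", "t2", "t3", "t4",
                                  "p1", "p2", "p3", "p4",
                                  "n1", "n2", "n3", "n4"),
                    gene = c("g1", "g1", "g2", "g3", "g4",
                             "g1", "g2", "g3", "g4",
                             "g1", "g2", "g3", "g4"))
  mrna_std <- fake_calls(c("t1a", "t1b", "t2", "t3", "t4"),
                         c(FALSE, TRUE, TRUE, FALSE, FALSE),
                         phase = c(NA, 4, 7, NA, NA), amplitude = 1)
  te_std <- fake_calls(c("p1", "p2", "p3", "p4"),
                       c(TRUE, TRUE, FALSE, FALSE),
                       phase = c(7, 4, NA, NA), amplitude = c(2, 0.5, NA, NA))
  ne_std <- fake_calls(c("n1", "n2", "n3", "n4"),
                       c(TRUE, FALSE, TRUE, FALSE),
                       phase = c(20, NA, 21, NA), amplitude = 0.4)
  none <- function(f) { f$consensus_rhythmic <- FALSE; f }
  list(mrna = stack_conditions(mrna_std, none(mrna_std)),
       te = stack_conditions(te_std, none(te_std)),
       ne = stack_conditions(ne_std, none(ne_std)),
       map = map)
}

test_that("gene join applies the ANY rule over a gene's series", {
  tj <- toy_join()
  j <- join_layers(tj$mrna, tj$te, tj$ne, tj$map)
  expect_equal(nrow(j), 4)
  # g1 rhythmic at mRNA because one of its two transcripts is
  expect_true(j$rhythmic_mrna_std[j$gene == "g1"])
  expect_equal(j$phase_mrna_std[j$gene == "g1"], 4)
  expect_equal(j$rhythmic_te_std, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(j$rhythmic_ne_std, c(TRUE, FALSE, TRUE, FALSE))
  # nothing rhythmic under ECD in this toy
  expect_false(any(j$rhythmic_mrna_ecd))
})

test_that("join matches a brute-force nested-loop join on random toys", {
  set.seed(33)
  genes <- sprintf("g%02d", 1:12)
  map <- data.frame(series_id = sprintf("s%03d", 1:36),
                    gene = sample(genes, 36, replace = TRUE))
  mk <- function(ids) {
    std <- fake_calls(ids, runif(length(ids)) < 0.4,
                      phase = runif(length(ids), 0, 24),
                      amplitude = runif(length(ids), 0.1, 2))
    ecd <- fake_calls(ids, runif(length(ids)) < 0.4,
                      phase = runif(length(ids), 0, 24),
                      amplitude = runif(length(ids), 0.1, 2))
    stack_conditions(std, ecd)
  }
  mrna <- mk(map$series_id[1:16])
  te <- mk(map$series_id[17:26])
  ne <- mk(map$series_id[27:36])
  j <- join_layers(mrna, te, ne, map)
  gene_of <- function(ids) map$gene[match(ids, map$series_id)]
  expected_universe <- sort(intersect(
    unique(gene_of(mrna$series_id)),
    union(unique(gene_of(te$series_id)), unique(gene_of(ne$series_id)))))
  expect_equal(j$gene, expected_universe)
  for (g in j$gene) {
    for (cond in c("STD", "ECD")) {
      rows <- mrna[mrna$condition == cond & gene_of(mrna$series_id) == g, ]
      expect_equal(j[[paste0("rhythmic_mrna_", tolower(cond))]][j$gene == g],
                   any(rows$consensus_rhythmic))
    }
  }
  expect_error(join_layers(mrna, te, ne, map[-1, ]), "unmapped")
})

test_that("overlap percentages match hand enumeration on the toy join", {
  tj <- toy_join()
  j <- join_layers(tj$mrna, tj$te, tj$ne, tj$map)
  ov <- overlap_percentages(j, "STD")
  # rhythmic mRNA: g1, g2; both have rhythmic TE -> 100%
  expect_equal(ov$pct_rhythmic_mrna_with_rhythmic_te, 100)
  expect_equal(ov$pct_rhythmic_te_with_rhythmic_mrna, 100)
  # rhythmic TE: g1, g2; NE rhythmic: g1, g3 -> TE with NE = 1/2
  expect_equal(ov$pct_rhythmic_te_with_rhythmic_ne, 50)
  expect_equal(ov$pct_rhythmic_ne_with_rhythmic_te, 50)
  # NE-rhythmic and not TE-rhythmic: g3
  expect_equal(ov$n_gor_pta, 1)
  expect_equal(ov$pct_contribution_chain,
               contribution_chain(50, 100))
  # zero denominators give NA (ECD has no rhythmic gene)
  ov_ecd <- overlap_percentages(j, "ECD")
  expect_true(is.na(ov_ecd$pct_rhythmic_ne_with_rhythmic_te))
  # complementarity: NE-only plus NE-with-TE partitions rhythmic NE
  n_ne <- sum(j$rhythmic_ne_std & j$has_te & j$has_ne)
  expect_equal(ov$n_gor_pta +
                 sum(j$rhythmic_ne_std & j$rhythmic_te_std & j$has_te), n_ne)
})

test_that("a nested NE-rhythmic set yields a 100% overlap", {
  tj <- toy_join()
  # make NE rhythmic only where TE is rhythmic (g1)
  tj$ne$consensus_rhythmic[tj$ne$series_id %in% c("n3")] <- FALSE
  j <- join_layers(tj$mrna, tj$te, tj$ne, tj$map)
  ov <- overlap_percentages(j, "STD")
  expect_equal(ov$pct_rhythmic_ne_with_rhythmic_te, 100)
  expect_equal(ov$n_gor_pta, 0)
})

test_that("the contribution chain multiplies its links", {
  expect_equal(contribution_chain(14, 27), 3.8)
  expect_equal(contribution_chain(100, 100), 100.0)
  # chaining rounded inputs: 6% x 48% gives 2.9 (not the count-level 2.8)
  expect_equal(contribution_chain(6, 48), 2.9)
  expect_error(contribution_chain(-1, 50), "\\[0, 100\\]")
  # monotone non-decreasing in each argument
  grid <- seq(0, 100, by = 10)
  expect_true(all(diff(vapply(grid, contribution_chain,
                              numeric(1), pct_te_with_rhythmic_mrna = 37))
                  >= 0))
})

test_that("lead/lag and amplitude-ratio counts match brute-force", {
  set.seed(8)
  n <- 20
  map <- data.frame(series_id = c(sprintf("t%02d", 1:n),
                                  sprintf("p%02d", 1:n),
                                  sprintf("n%02d", 1:n)),
                    gene = rep(sprintf("g%02d", 1:n), 3))
  ph_t <- runif(n, 0, 24); ph_p <- runif(n, 0, 24)
  am_t <- runif(n, 0.1, 2); am_p <- runif(n, 0.1, 2)
  mrna <- stack_conditions(
    fake_calls(sprintf("t%02d", 1:n), TRUE, ph_t, am_t),
    fake_calls(sprintf("t%02d", 1:n), FALSE))
  te <- stack_conditions(
    fake_calls(sprintf("p%02d", 1:n), TRUE, ph_p, am_p),
    fake_calls(sprintf("p%02d", 1:n), FALSE))
  ne <- stack_conditions(
    fake_calls(sprintf("n%02d", 1:n), FALSE),
    fake_calls(sprintf("n%02d", 1:n), FALSE))
  j <- join_layers(mrna, te, ne, map)
  ll <- lead_lag_ratio(j, "STD")
  d <- (ph_p - ph_t) %% 24
  expect_equal(ll$n_lead, sum(d > 0 & d < 12))
  expect_equal(ll$n_lag, sum(!(d > 0 & d < 12)))
  ar <- amplitude_ratio_classification(j, "STD")
  expect_equal(ar$n_protein_higher, sum(am_p > am_t))
  expect_equal(ar$n_protein_lower, sum(am_p <= am_t))
  # no doubly-rhythmic genes under ECD -> NA
  expect_true(is.na(lead_lag_ratio(j, "ECD")$ratio))
  expect_true(is.na(amplitude_ratio_classification(j, "ECD")$ratio))
})

test_that("lead/lag tie and orientation conventions hold", {
  map <- data.frame(series_id = c("t1", "t2", "p1", "p2", "n1", "n2"),
                    gene = c("g1", "g2", "g1", "g2", "g1", "g2"))
  mrna <- stack_conditions(fake_calls(c("t1", "t2"), TRUE, c(4, 7), 1),
                           fake_calls(c("t1", "t2"), FALSE))
  te <- stack_conditions(fake_calls(c("p1", "p2"), TRUE, c(7, 4), 1),
                         fake_calls(c("p1", "p2"), FALSE))
  ne <- stack_conditions(fake_calls(c("n1", "n2"), FALSE),
                         fake_calls(c("n1", "n2"), FALSE))
  j <- join_layers(mrna, te, ne, map)
  ll <- lead_lag_ratio(j, "STD")
  # transcript 4 -> protein 7: lead; transcript 7 -> protein 4: lag
  expect_equal(ll$n_lead, 1)
  expect_equal(ll$n_lag, 1)
  # equal amplitudes count as protein-lower (strict >)
  ar <- amplitude_ratio_classification(j, "STD")
  expect_equal(ar$n_protein_higher, 0)
  expect_equal(ar$n_protein_lower, 2)
})

test_that("disjoint id universes yield an explicit empty join", {
  map <- data.frame(series_id = c("t1", "p1"), gene = c("gA", "gB"))
  mrna <- stack_conditions(fake_calls("t1", TRUE, 3, 1),
                           fake_calls("t1", FALSE))
  te <- stack_conditions(fake_calls("p1", FALSE), fake_calls("p1", FALSE))
  ne <- stack_conditions(fake_calls("p1", FALSE), fake_calls("p1", FALSE))
  j <- join_layers(mrna, te, ne, map)
  expect_equal(nrow(j), 0)
  expect_error(overlap_percentages(j, "STD"), "empty")
})
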