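mini_domains <- function(seed = 5L, ul = 80L) {
  set.seed(seed)
  u <- random_dna(ul)
  list(A = random_dna(1200), B1 = random_dna(250), I = random_dna(300),
       B2 = random_dna(1300), ST_large = st_small_array(u, 2L, 3L),
       ST_small_f = strrep(u, 3L), ST_small_r = strrep(u, 4L),
       unit = u)
}

st_small_array <- function(u, nf, nr) paste0(strrep(u, nf),
                                             strrep(revcomp(u), nr))

test_that("the standard layout yields the canonical junction names", {
  d <- mini_domains()
  m <- build_cassette_model(d, palindromic_cassette_layout())
  expect_setequal(unique(m$junctions$name),
                  c("STs-A", "A-B", "B-I", "I-B", "B-ST", "INV"))
  expect_equal(sum(m$junctions$name == "INV"), 1L)
  expect_equal(sum(m$junctions$name == "A-B"), 2L)   # primed copy pooled
  # boundary bookkeeping: last boundary equals total length
  expect_equal(m$layout$stop[nrow(m$layout)], nchar(m$sequence))
  expect_equal(sum(m$layout$stop - m$layout$start), nchar(m$sequence))
  # single-domain model has no junctions
  m1 <- build_cassette_model(list(A = d$A),
                             data.frame(domain = "A", orientation = "+",
                                        part = "A"))
  expect_equal(nrow(m1$junctions), 0L)
  expect_error(build_cassette_model(d, data.frame()[0, ]), "empty")
})

test_that("spanning reads are counted only with both anchors", {
  d <- mini_domains()
  m <- build_cassette_model(d, palindromic_cassette_layout())
  j_ab <- m$junctions$position[m$junctions$name == "A-B"][1L]
  sq <- m$sequence
  reads <- c(spanning = substr(sq, j_ab - 150 + 1, j_ab + 150),
             terminating = substr(sq, j_ab - 300 + 1, j_ab),
             short_anchor = substr(sq, j_ab - 99 + 1, j_ab + 200))
  sup <- count_junction_support(reads, m, min_anchor = 100L)
  expect_equal(sup[sup$junction == "A-B", ]$n_spanning, 1L)
  expect_error(count_junction_support(reads, m, min_anchor = 0L),
               "min_anchor")
  # reads that avoid all junctions support nothing
  far <- c(inside_A = substr(sq, m$layout$start[2L] + 10L,
                             m$layout$start[2L] + 400L))
  sup0 <- count_junction_support(far, m, min_anchor = 100L)
  expect_true(all(sup0$n_spanning == 0L))
})

test_that("palindromic tandem simulation shows the half-abundance inversion", {
  g <- build_genomes(small_sim_config(units = 3L, seed = 13L))
  long <- simulate_reads(g$resistant, "long", coverage = 40,
                         length_params = list(median = 4000), seed = 14L)
  model <- cassette_model_from_truth(g$truth)
  sup <- count_junction_support(long, model, min_anchor = 100L, seed = 15L)
  expect_true(all(sup$n_spanning > 0L))
  inv <- sup$n_spanning[sup$junction == "INV"]
  others <- sup$n_spanning[sup$junction != "INV"]
  ratio <- inv / median(others)
  expect_gte(ratio, 0.4)
  expect_lte(ratio, 0.6)
  expect_equal(as.character(infer_architecture(sup)), "palindromic_tandem")
  # support scales roughly linearly with coverage
  long2 <- simulate_reads(g$resistant, "long", coverage = 20,
                          length_params = list(median = 4000), seed = 16L)
  sup2 <- count_junction_support(long2, model, min_anchor = 100L,
                                 seed = 17L)
  tot_ratio <- sum(sup$n_spanning) / sum(sup2$n_spanning)
  expect_gt(tot_ratio, 1.5)
  expect_lt(tot_ratio, 2.6)
})

test_that("architecture calls follow the characteristic ratio signature", {
  # a characteristic support profile: INV 265, other junctions 461-556
  sup <- data.table::data.table(
    junction = c("STs-A", "A-B", "B-I", "I-B", "B-ST", "INV"),
    n_spanning = c(545L, 466L, 466L, 466L, 545L, 265L),
    n_instances = c(2L, 2L, 2L, 2L, 2L, 1L))
  sup[, relative_abundance := n_spanning / min(n_spanning)]
  call <- infer_architecture(sup)
  expect_equal(as.character(call), "palindromic_tandem")
  expect_lt(abs(attr(call, "inv_ratio") - 0.5), 0.15)
  # all junctions equal within noise: simple tandem
  sup2 <- data.table::copy(sup)[, n_spanning := c(500L, 480L, 510L, 495L,
                                                  505L, 490L)]
  expect_equal(as.character(infer_architecture(sup2)), "simple_tandem")
  # a zero-support domain junction is unsupported
  sup3 <- data.table::copy(sup)[junction == "A-B", n_spanning := 0L]
  expect_equal(as.character(infer_architecture(sup3)), "unsupported")
  expect_error(infer_architecture(sup[0L]), "empty")
})

test_that("a non-inverted tandem array reads as simple tandem", {
  d <- mini_domains(seed = 21L)
  # simple tandem: three forward copies separated by the small ST array
  lay1 <- data.frame(domain = c("ST_large", "A", "B", "I", "B", "ST_small"),
                     orientation = "+",
                     part = c("ST_large", "A", "B1", "I", "B2",
                              "ST_small_f"))
  lay <- rbind(lay1, lay1[-1L, ], lay1[-1L, ])
  m <- build_cassette_model(d, lay)
  set.seed(22)
  host <- paste0(random_dna(2000), m$sequence, random_dna(2000))
  gm <- genome_model(c(Chr1 = host))
  long <- simulate_reads(gm, "long", coverage = 40,
                         length_params = list(median = 2500), seed = 23L)
  sup <- count_junction_support(long, m, min_anchor = 100L, seed = 24L)
  expect_false("INV" %in% sup$junction)
  expect_equal(as.character(infer_architecture(sup)), "simple_tandem")
})

test_that("alternative assemblies are arbitrated by spanning reads", {
  set.seed(30)
  left <- random_dna(2500); right1 <- random_dna(2500)
  right2 <- random_dna(2500)
  cand <- c(model1 = paste0(left, right1), model2 = paste0(left, right2))
  gm <- genome_model(c(Chr1 = cand[["model1"]]))
  reads <- simulate_reads(gm, "long", coverage = 25,
                          length_params = list(median = 1500), seed = 31L)
  v <- validate_alternatives(cand, reads, positions = 2500L,
                             min_anchor = 100L)
  expect_equal(v$winner, "model1")
  n1 <- v$counts[v$counts$candidate == "model1", ]$n_spanning
  n2 <- v$counts[v$counts$candidate == "model2", ]$n_spanning
  expect_gt(n1, 5 * max(1L, n2))
  # identical candidates are inconclusive
  v2 <- validate_alternatives(c(a = cand[["model1"]], b = cand[["model1"]]),
                              reads, positions = 2500L)
  expect_true(is.na(v2$winner))
  expect_equal(v2$counts$n_spanning[1L], v2$counts$n_spanning[2L])
  # zero reads: inconclusive
  v3 <- validate_alternatives(cand, character(0), positions = 2500L)
  expect_true(is.na(v3$winner))
  expect_error(validate_alternatives(character(0), reads, 1L),
               "candidates")
})

test_that("self dot-plot recovers inverted and tandem repeat structure", {
  set.seed(33)
  core <- random_dna(600)
  seq_inv <- paste0(random_dna(800), core, random_dna(400), revcomp(core),
                    random_dna(800))
  dp <- self_dotplot(seq_inv, k = 15L)
  inv_hits <- dp[dp$orientation == "-" & dp$length >= 600L, ]
  expect_gte(nrow(inv_hits), 1L)
  expect_equal(inv_hits$pos1[1L], 800L)
  expect_equal(inv_hits$pos2[1L], 1800L)
  # tandem array: off-diagonal chains at multiples of the unit length
  unit <- random_dna(200)
  dp2 <- self_dotplot(paste0(strrep(unit, 5L), random_dna(300)), k = 15L)
  fwd <- dp2[dp2$orientation == "+", ]
  offs <- unique(fwd$pos2 - fwd$pos1)
  expect_true(all(offs %% 200L == 0L))
  # random sequence: chance off-diagonal matches are essentially absent
  dp3 <- self_dotplot(random_dna(10000), k = 15L)
  expect_equal(nrow(dp3[dp3$orientation == "+", ]), 0L)
  expect_error(self_dotplot("ACGT", k = 15L), "shorter")
})
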