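test_that("metaplot z-scoring handles degenerate and mirrored profiles", {
  flat <- list(g1 = rep(0.3, 50))
  mp <- metaplot(flat, c(g1 = 25), window = c(10, 10), min_genes = 1)
  expect_true(all(mp$z == 0))
  # two genes with mirror-image profiles cancel
  up <- c(rep(0.1, 25), rep(0.5, 25))
  mp2 <- metaplot(list(g1 = up, g2 = rev(up)), c(g1 = 25, g2 = 25),
                  window = c(5, 5), min_genes = 2)
  expect_true(all(abs(mp2$z) < 1e-9))
  # offsets with too few genes are dropped
  mp3 <- metaplot(list(g1 = up), c(g1 = 3), window = c(10, 10), min_genes = 1)
  expect_true(all(is.na(mp3$z[mp3$offset < -2])))
  expect_error(metaplot(list(), numeric(0)), class = "smstruct_value_error")
})

test_that("metaplot shows a planted accessible window upstream of the anchor", {
  set.seed(81)
  profiles <- list()
  anchors <- numeric(0)
  for (g in 1:12) {
    prof <- runif(200, 0.15, 0.25)
    prof[80:99] <- prof[80:99] + 0.4   # open window just upstream of 100
    profiles[[paste0("g", g)]] <- prof
    anchors[paste0("g", g)] <- 100
  }
  mp <- metaplot(profiles, anchors, window = c(40, 40), min_genes = 10)
  up_win <- mp$z[mp$offset >= -20 & mp$offset <= -1]
  outside <- mp$z[mp$offset > 0]
  expect_true(all(up_win > 1))
  expect_lt(max(outside), min(up_win))
  # i.i.d. noise keeps the averaged z-profile near zero overall
  noise <- lapply(1:20, function(g) runif(200))
  names(noise) <- paste0("n", 1:20)
  mp0 <- metaplot(noise, setNames(rep(100, 20), names(noise)),
                  window = c(40, 40), min_genes = 10)
  expect_lt(abs(mean(mp0$z)), 0.15)
})

test_that("region rates average consensus frequency within annotation intervals", {
  m_uniform <- mod_matrix(matrix(1, 4, 60))
  ann <- annotation("g1", 60, utr5 = c(1, 10), cds = c(11, 45),
                    utr3 = c(46, 60))
  rr <- region_rates(list(g1 = m_uniform), list(g1 = ann))
  expect_equal(unlist(rr[1, c("utr5", "cds", "utr3")]),
               c(utr5 = 1, cds = 1, utr3 = 1))
  ann2 <- annotation("g2", 60, utr5 = c(1, 10), cds = c(11, 60))
  rr2 <- region_rates(list(g2 = m_uniform), list(g2 = ann2))
  expect_true(is.na(rr2$utr3))
  # planted contrast is detected
  set.seed(83)
  mods <- list(); anns <- list()
  for (g in 1:8) {
    x <- cbind(matrix(rbinom(30 * 20, 1, 0.4), 30, 20),
               matrix(rbinom(30 * 40, 1, 0.2), 30, 40))
    nm <- paste0("g", g)
    mods[[nm]] <- mod_matrix(x)
    anns[[nm]] <- annotation(nm, 60, utr5 = c(1, 20), cds = c(21, 60))
  }
  tests <- region_rate_tests(region_rates(mods, anns))
  utr5_cds <- tests[tests$region_a == "utr5" & tests$region_b == "cds", ]
  expect_gt(utr5_cds$mean_a, utr5_cds$mean_b)
  expect_lt(utr5_cds$p.value, 0.01)
})

test_that("stop-codon groups are profiled separately and validated", {
  up <- c(rep(0.5, 100), rep(0.1, 100))
  profiles <- list(a = up, b = up, c = up)
  anchors <- c(a = 100, b = 100, c = 100)
  codons <- c(a = "UAA", b = "UAA", c = "UAA")
  grouped <- grouped_stop_profiles(profiles, anchors, codons,
                                   window = c(20, 20), min_genes = 1)
  plain <- metaplot(profiles, anchors, window = c(20, 20), min_genes = 1)
  expect_equal(grouped$z, plain$z)
  expect_error(grouped_stop_profiles(profiles, anchors,
                                     c(a = "UAA", b = "XXX", c = "UAG")),
               class = "smstruct_value_error")
  # constructed group ordering at the start of the 3'UTR
  mk <- function(level) c(rep(0.3, 100), rep(level, 30), rep(0.3, 70))
  profs <- list(u1 = mk(0.05), u2 = mk(0.05), t1 = mk(0.5), t2 = mk(0.5))
  anch <- setNames(rep(100, 4), names(profs))
  cods <- c(u1 = "UGA", u2 = "UGA", t1 = "UAA", t2 = "UAA")
  gp <- grouped_stop_profiles(profs, anch, cods, window = c(10, 20),
                              min_genes = 2)
  uga <- gp[gp$stop_codon == "UGA" & gp$offset > 0, ]
  uaa <- gp[gp$stop_codon == "UAA" & gp$offset > 0, ]
  expect_true(all(uga$z < uaa$z))
})

test_that("motif profiles average over hits and truncate at boundaries", {
  prof <- seq(0, 1, length.out = 100)
  hits <- tibble::tibble(gene = "g1", motif = "AAUAAA", start = 60)
  mp <- motif_profile(list(g1 = prof), hits, up = 10, down = 5)
  expect_equal(mp$rate[mp$offset == 0], prof[60])
  expect_equal(mp$rate[mp$offset == -10], prof[50])
  # hit near the start leaves early offsets uncovered
  hits2 <- tibble::tibble(gene = "g1", motif = "AAUAAA", start = 10)
  mp2 <- motif_profile(list(g1 = prof), hits2, up = 50, down = 20)
  expect_true(all(is.na(mp2$rate[mp2$offset < -9])))
  expect_true(all(!is.na(mp2$rate[mp2$offset >= -9])))
  # planted peak at the motif start
  set.seed(85)
  profs <- list(); rows <- list()
  for (g in 1:10) {
    p <- runif(200, 0.1, 0.3)
    p[100:110] <- p[100:110] + 0.5
    nm <- paste0("g", g)
    profs[[nm]] <- p
    rows[[g]] <- tibble::tibble(gene = nm, motif = "AAUAAA", start = 100)
  }
  mp3 <- motif_profile(profs, dplyr::bind_rows(rows), up = 50, down = 20)
  expect_gt(mp3$rate[mp3$offset == 0], max(mp3$rate[mp3$offset < -5]))
})

test_that("gene ranking is descending with stable ties", {
  mods <- list(
    b_gene = mod_matrix(matrix(c(1, 0, 0, 0), 2, 2)),   # rate 0.25
    a_gene = mod_matrix(matrix(c(1, 1, 0, 0), 2, 2)),   # rate 0.5
    c_gene = mod_matrix(matrix(c(1, 1, 0, 0), 2, 2))    # rate 0.5 (tie)
  )
  gr <- gene_rank(mods)
  expect_equal(gr$gene, c("a_gene", "c_gene", "b_gene"))
  expect_equal(gr$rank, 1:3)
  single <- gene_rank(mods["b_gene"])
  expect_equal(single$rank, 1L)
})

test_that("annotation files round-trip through the BED-like format", {
  tx <- fixture_transcriptome(n_genes = 3, gene_length = 240, seed = 2)
  path <- withr::local_tempfile(fileext = ".bed")
  write_annotation(tx$annotations, path)
  back <- read_annotation(path)
  for (nm in names(tx$annotations)) {
    expect_equal(back[[nm]]$utr5, tx$annotations[[nm]]$utr5)
    expect_equal(back[[nm]]$cds, tx$annotations[[nm]]$cds)
    expect_equal(back[[nm]]$stop_codon, tx$annotations[[nm]]$stop_codon)
    expect_equal(back[[nm]]$stop_codon_id, tx$annotations[[nm]]$stop_codon_id)
    expect_equal(back[[nm]]$motifs$start, tx$annotations[[nm]]$motifs$start)
  }
  expect_error(annotation("g", 100, utr5 = c(1, 20), cds = c(15, 60)),
               class = "smstruct_value_error")
  expect_error(annotation("g", 100, stop_codon = 150),
               class = "smstruct_value_error")
})
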