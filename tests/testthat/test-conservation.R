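test_that("hit retention uses matched bases with an inclusive 20-base boundary", {
  hits <- make_hits(
    list(qs = 1, qe = 25, ss = 100, se = 124, len = 25, id = 100),  # 25 kept
    list(qs = 1, qe = 25, ss = 100, se = 124, len = 25, id = 60),   # 15 out
    list(qs = 1, qe = 19, ss = 100, se = 118, len = 19, id = 100),  # 19 out
    list(qs = 1, qe = 20, ss = 100, se = 119, len = 20, id = 100))  # 20 kept
  kept <- retain_hits(hits, gradr_config())
  expect_equal(nrow(kept), 2)
  expect_setequal(kept$align_length, c(25, 20))

  # raw-alignment-length reading keeps the 60%-identity hit too
  kept_len <- retain_hits(hits, gradr_config(), mode = "length")
  expect_equal(nrow(kept_len), 3)
})

test_that("BLAST tabular parsing validates rows and normalises query strand", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("q1\tchr1\t95.5\t100\t4\t1\t200\t101\t5000\t4901\t1e-20\t180",
               "q1\tchr2\t88\t50\t6\t0\t1\t50\t900\t949\t1e-5\t60"), path)
  hits <- read_blast_tab(path)
  expect_equal(nrow(hits), 2)
  expect_true(all(hits$q_start <= hits$q_end))
  expect_equal(hits$q_start[1], 101)

  writeLines(c("q1\tchr1\t95.5\t100\t4\t1\t200\t101\t5000\t4901\t1e-20\t180",
               "q1\tchr1\tbroken"), path)
  expect_error(read_blast_tab(path), "line 2")

  # empty file: zero hits, not an error
  writeLines(character(), path)
  expect_equal(nrow(read_blast_tab(path)), 0)
})

test_that("percent conservation matches the per-position oracle", {
  cfg <- gradr_config()
  # spec'd scenario: overlap resolved by the higher-identity hit
  hits <- make_hits(list(qs = 1, qe = 30, ss = 100, se = 129, id = 100),
                    list(qs = 21, qe = 60, ss = 200, se = 239, id = 90))
  got <- percent_conservation(100, hits)
  expect_equal(got, oracle_pct_conservation(100, hits))
  # by hand: 20 bases at 100%, 10 overlap bases at 100%, 30 at 90%
  expect_equal(got, (20 + 10 + 30 * 0.9))

  expect_equal(percent_conservation(100, hits[0, ]), 0)
  full <- make_hits(list(qs = 1, qe = 100, ss = 1, se = 100, id = 100))
  expect_equal(percent_conservation(100, full), 100)

  # unweighted mode counts covered positions only
  expect_equal(percent_conservation(100, hits, weighted = FALSE), 60)

  # randomised agreement with the oracle, both modes
  set.seed(77)
  for (i in 1:25) {
    n <- sample(1:8, 1)
    qs <- sample(1:80, n, replace = TRUE)
    h <- do.call(make_hits, lapply(seq_len(n), function(j) {
      list(qs = qs[j], qe = min(100, qs[j] + sample(5:40, 1)),
           ss = 1000 + j * 50, se = 1000 + j * 50 + 30,
           id = sample(70:100, 1))
    }))
    expect_equal(percent_conservation(100, h),
                 oracle_pct_conservation(100, h), tolerance = 1e-12)
    expect_equal(percent_conservation(100, h, weighted = FALSE),
                 oracle_pct_conservation(100, h, weighted = FALSE),
                 tolerance = 1e-12)
  }
})

test_that("percent conservation is invariant to hit order and to splitting a hit", {
  hits <- make_hits(list(qs = 10, qe = 50, ss = 100, se = 140, id = 95),
                    list(qs = 40, qe = 80, ss = 300, se = 340, id = 85))
  expect_equal(percent_conservation(100, hits),
               percent_conservation(100, hits[2:1, ]))
  whole <- make_hits(list(qs = 10, qe = 50, ss = 100, se = 140, id = 90))
  split <- make_hits(list(qs = 10, qe = 30, ss = 100, se = 120, id = 90),
                     list(qs = 31, qe = 50, ss = 121, se = 140, id = 90))
  expect_equal(percent_conservation(100, whole),
               percent_conservation(100, split))
})

test_that("window selection maximises query coverage within 100 kb", {
  cfg <- gradr_config()
  # locus A covers query 1-40; locus B, 200 kb away, covers 1-25
  hits <- make_hits(list(qs = 1, qe = 40, ss = 10000, se = 10039, id = 95),
                    list(qs = 1, qe = 25, ss = 210000, se = 210024, id = 95))
  w <- select_ortholog_window(hits, cfg)
  expect_equal(w$window_start, 10000)
  expect_equal(w$coverage, 40)

  # synteny hint on locus B overrides the coverage choice
  w2 <- select_ortholog_window(hits, cfg,
                               synteny_hint = list(subject_id = "chr1",
                                                   start = 205000,
                                                   end = 215000))
  expect_equal(w2$window_start, 210000)
  expect_equal(w2$coverage, 25)

  # single cluster: its bounding window is selected
  clus <- make_hits(list(qs = 1, qe = 30, ss = 5000, se = 5029, id = 90),
                    list(qs = 50, qe = 90, ss = 12000, se = 12040, id = 90))
  w3 <- select_ortholog_window(clus, cfg)
  expect_equal(w3$window_start, 5000)
  expect_equal(w3$window_end, 12040)
  expect_equal(nrow(w3$hits), 2)

  # no hits: scored 0 with an empty window, not an error
  w0 <- select_ortholog_window(clus[0, ], cfg)
  expect_equal(w0$coverage, 0)
  expect_true(is.na(w0$subject_id))
})

test_that("window selection agrees with exhaustive enumeration on random hit sets", {
  cfg <- gradr_config()
  set.seed(99)
  for (i in 1:30) {
    n <- sample(2:20, 1)
    h <- do.call(make_hits, lapply(seq_len(n), function(j) {
      qs <- sample(1:150, 1)
      ss <- sample(1:400000, 1)
      list(qs = qs, qe = qs + sample(20:60, 1),
           s = sample(c("chr1", "chr2"), 1),
           ss = ss, se = ss + sample(20:60, 1), id = sample(75:100, 1))
    }))
    got <- select_ortholog_window(h, cfg)
    exp <- oracle_window(h, cfg$window_bp)
    expect_equal(got$coverage, exp$coverage)
    expect_setequal(rownames(got$hits), rownames(h)[exp$idx])
  }
})

test_that("adding a hit never decreases window coverage", {
  cfg <- gradr_config()
  set.seed(55)
  base <- do.call(make_hits, lapply(1:5, function(j) {
    qs <- sample(1:100, 1)
    list(qs = qs, qe = qs + 20, ss = 1000 + j * 100,
         se = 1030 + j * 100, id = 90)
  }))
  cov0 <- select_ortholog_window(base, cfg)$coverage
  extra <- rbind(base, make_hits(list(qs = 140, qe = 170, ss = 2000,
                                      se = 2030, id = 90)))
  expect_gte(select_ortholog_window(extra, cfg)$coverage, cov0)
})

test_that("conservation table covers every query x species with quantile summaries", {
  cfg <- gradr_config()
  hits_sp1 <- rbind(
    make_hits(list(q = "lnc1", qs = 1, qe = 60, ss = 100, se = 159,
                   id = 95)),
    make_hits(list(q = "lnc2", qs = 1, qe = 40, ss = 5000, se = 5039,
                   id = 80)))
  hits_sp2 <- make_hits(list(q = "lnc1", qs = 10, qe = 40, ss = 700,
                             se = 730, id = 85))
  tbl <- conservation_table(
    list(macaque = hits_sp1, mouse = hits_sp2,
         chicken = hits_sp1[0, ]),
    query_lengths = c(lnc1 = 100, lnc2 = 80), cfg)
  expect_equal(nrow(tbl), 6)
  # species without hits scores 0 for every query
  expect_equal(tbl$pct_base_conservation[tbl$species == "chicken"], c(0, 0))
  # per-row agreement with the per-position oracle
  i <- tbl$species == "macaque" & tbl$query_id == "lnc1"
  expect_equal(tbl$pct_base_conservation[i],
               oracle_pct_conservation(100, hits_sp1[1, ]))

  smry <- conservation_summary(tbl)
  for (s in smry$species) {
    v <- sort(tbl$pct_base_conservation[tbl$species == s])
    n <- length(v)
    med <- if (n %% 2 == 1) v[(n + 1) / 2] else mean(v[n / 2 + 0:1])
    expect_equal(smry$median[smry$species == s], med)
  }
  expect_error(conservation_table(list(sp = hits_sp1),
                                  c(100, 80), cfg), "named")
})
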