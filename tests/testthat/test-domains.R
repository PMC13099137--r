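test_that("domain caller finds a planted enrichment and nothing else", {
  set.seed(1)
  x <- c(rpois(200, 2), rpois(20, 20), rpois(200, 2))
  d <- call_domains(x, domain_params(bin_size = 750))
  expect_equal(nrow(d), 1L)
  # Jaccard overlap with the plant (bins 201-220) >= 0.8
  plant <- 201:220
  called <- d$first_bin[1]:d$last_bin[1]
  jac <- length(intersect(plant, called)) / length(union(plant, called))
  expect_gte(jac, 0.8)
  expect_gte(d$mean_posterior[1], 0.4)

  # constant track -> no domains
  expect_equal(nrow(call_domains(rep(3, 100))), 0L)
  # all-zero track -> no domains
  expect_equal(nrow(call_domains(rep(0, 100))), 0L)
  # posterior_min = 1 suppresses noisy calls
  d2 <- call_domains(x, domain_params(bin_size = 750, posterior_min = 1))
  expect_equal(nrow(d2), 0L)
})

test_that("emitted domains are sorted and non-overlapping", {
  set.seed(2)
  x <- rpois(2000, 1)
  for (s in c(300, 900, 1500)) x[s:(s + 14)] <- rpois(15, 15)
  d <- call_domains(x, domain_params(bin_size = 750))
  expect_true(all(diff(d$start) > 0))
  expect_true(all(head(d$end, -1) <= tail(d$start, -1)))
})

test_that("subpeak detection scores against the local background", {
  set.seed(3)
  # a domain with one sharp interior peak and one flat domain
  x <- rpois(300, 1)
  x[50:69] <- rpois(20, 12)       # broad domain
  x[58:60] <- rpois(3, 120)       # sharp subpeak inside
  x[200:219] <- rpois(20, 12)     # flat domain, no subpeak
  d <- call_domains(x, domain_params(bin_size = 750))
  expect_gte(nrow(d), 2)
  ref <- refine_subpeaks(d, x, domain_params(bin_size = 750))
  expect_true("subpeak" %in% ref$source)
  sub <- ref[ref$source == "subpeak", ]
  expect_true(any(sub$first_bin <= 58 & sub$last_bin >= 60))
  # the parent of the subpeak is gone; the flat domain passes through
  expect_false(any(ref$source == "domain" &
                     ref$first_bin <= 58 & ref$last_bin >= 60))
  expect_true(any(ref$source == "domain" & ref$first_bin >= 195))
  # merge rule is exhaustive: no remaining domain contains a subpeak
  doms <- ref[ref$source == "domain", ]
  for (i in seq_len(nrow(doms))) {
    expect_false(any(sub$start >= doms$start[i] & sub$end <= doms$end[i]))
  }

  # with an unreachable score threshold the domains pass unchanged
  ref2 <- refine_subpeaks(d, x, domain_params(bin_size = 750),
                          enrichment_min = 1e9)
  expect_equal(ref2[, names(d)], d)
})

test_that("merge rule on the two-domain example is exact", {
  domains <- data.frame(chrom = "c1", start = c(0, 20000),
                        end = c(10000, 25000), strand = ".",
                        source = "domain")
  subpeaks <- data.frame(chrom = "c1", start = 2000, end = 3000,
                         strand = ".", source = "subpeak", score = 60)
  out <- merge_subpeaks(domains, subpeaks)
  expect_equal(nrow(out), 2L)
  expect_equal(out$start, c(2000, 20000))
  expect_equal(out$end, c(3000, 25000))
  expect_equal(out$source, c("subpeak", "domain"))

  # no subpeaks: identity
  out0 <- merge_subpeaks(domains, subpeaks[0, ])
  expect_equal(out0$start, domains$start)
})

test_that("domain classes follow promoter > gene_covering > genic priority", {
  genes <- toy_genes()
  # gA: + strand, tss 1000 -> promoter window [800, 1300)
  doms <- data.frame(chrom = "chr1",
                     start = c(800, 10000, 100000, 2000),
                     end = c(1300, 13400, 100500, 2500),
                     strand = ".")
  ann <- annotate_domains(doms, genes)
  expect_equal(ann$class[1], "promoter")
  # covers 85% of gB (3400 of 4000 bp) without reaching its promoter
  # window ([13700, 14200) on the minus strand)
  expect_equal(ann$class[2], "gene_covering")
  # far from all genes -> intergenic with nearest gene assigned
  expect_equal(ann$class[3], "intergenic")
  expect_equal(ann$genes[3], "gC")
  # inside gA body but not its promoter, covering < 80%
  expect_equal(ann$class[4], "genic")
  expect_equal(ann$genes[4], "gA")

  # minus-strand promoter window: gB tss 13999 -> [13700, 14200)
  doms2 <- data.frame(chrom = "chr1", start = 14000, end = 14150,
                      strand = ".")
  expect_equal(annotate_domains(doms2, genes)$class, "promoter")

  # gene without explicit strand is an error
  g2 <- genes; g2$strand[1] <- "."
  expect_error(annotate_domains(doms, g2), "strand")
})

test_that("mark partition assigns every domain exactly one class", {
  a <- data.frame(chrom = "c1", start = c(0, 1000), end = c(100, 1100),
                  strand = ".")
  b <- data.frame(chrom = "c1", start = c(50, 5000), end = c(150, 5100),
                  strand = ".")
  p <- partition_marks(a, b, labels = c("K27", "K4"))
  expect_equal(nrow(p), 4L)
  expect_equal(p$partition[p$set == "K27"], c("co_enriched", "K27_unique"))
  expect_equal(p$partition[p$set == "K4"], c("co_enriched", "K4_unique"))

  # identical lists -> all co-enriched; disjoint -> all unique
  pi <- partition_marks(a, a)
  expect_true(all(pi$partition == "co_enriched"))
  pd <- partition_marks(a[2, ], b[2, ])
  expect_true(all(grepl("unique", pd$partition)))
})
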