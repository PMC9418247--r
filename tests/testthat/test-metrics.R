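test_that("loss-of-function filter keeps exactly the four LoF classes, in order", {
  v <- make_variants(
    make_variant(gene = "TP53", effect = "missense", pos = 1),
    make_variant(gene = "APC", effect = "synonymous", pos = 2),
    make_variant(gene = "SMAD4", effect = "nonsense", pos = 3),
    make_variant(gene = "GNAS", effect = "other", pos = 4),
    make_variant(gene = "ATM", effect = "frameshift", ref = "AT", alt = "A", pos = 5),
    make_variant(gene = "MYC", effect = "inframe_indel", ref = "ATT", alt = "A", pos = 6)
  )
  kept <- filter_lof(v)
  expect_equal(kept$effect, c("missense", "nonsense", "frameshift", "inframe_indel"))
  expect_equal(kept$pos, c(1, 3, 5, 6))
  expect_equal(nrow(filter_lof(v[0, ])), 0)
  syn <- do.call(rbind, replicate(10, make_variant(effect = "synonymous"),
                                  simplify = FALSE))
  expect_equal(nrow(filter_lof(syn)), 0)
})

test_that("bTMB counts somatic coding SNVs only and excludes CHIP genes", {
  nine <- do.call(rbind, lapply(1:9, function(i)
    make_variant(gene = "TP53", pos = i, effect = "missense")))
  expect_equal(compute_btmb(nine, panel_spec()), 9 / 2.4)

  with_chip <- rbind(nine, make_variant(gene = "DNMT3A", pos = 100))
  expect_equal(compute_btmb(with_chip, panel_spec()), 9 / 2.4)

  # synonymous SNVs count; indels and germline never do
  mixed <- rbind(
    nine,
    make_variant(effect = "synonymous", gene = "APC", pos = 50),
    make_variant(effect = "frameshift", ref = "AT", alt = "A", pos = 51),
    make_variant(origin = "germline", gene = "ATM", pos = 52)
  )
  expect_equal(compute_btmb(mixed, panel_spec()), 10 / 2.4)
  expect_equal(compute_btmb(mixed[0, ], panel_spec()), 0)
})

test_that("bTMB is additive over disjoint sets and inverse in panel size", {
  set.seed(7)
  a <- do.call(rbind, lapply(1:6, function(i)
    make_variant(gene = sample(c("TP53", "APC", "MYC"), 1), pos = i)))
  b <- do.call(rbind, lapply(1:4, function(i)
    make_variant(gene = "SMAD4", pos = 100 + i, effect = "nonsense")))
  p <- panel_spec()
  expect_equal(compute_btmb(rbind(a, b), p),
               compute_btmb(a, p) + compute_btmb(b, p))
  p2 <- panel_spec(effective_coding_size_mb = 2.4 * 3)
  expect_equal(compute_btmb(a, p2), compute_btmb(a, p) / 3)
})

test_that("sample CTF uses the maximum eligible autosomal somatic MAF", {
  v <- make_variants(
    make_variant(allele_fraction = 0.10, pos = 1),
    make_variant(allele_fraction = 0.05, pos = 2)
  )
  expect_equal(estimate_sample_ctf(v), maf_to_ctf(0.10))
  expect_equal(estimate_sample_ctf(v), 0.1818, tolerance = 1e-3)

  # sex-chromosome calls are ineligible
  x_only <- make_variant(chrom = "X", allele_fraction = 0.4, gene = "KDM6A")
  expect_true(is.na(estimate_sample_ctf(x_only)))

  # CNA-flagged calls are omitted before aggregation
  cna <- make_variants(
    make_variant(allele_fraction = 0.5, pos = 1),
    make_variant(allele_fraction = 0.9, pos = 2, cna_flag = TRUE)
  )
  expect_equal(estimate_sample_ctf(cna), 2 / 3)

  expect_error(estimate_sample_ctf(rbind(
    make_variant(sample_id = "S1"), make_variant(sample_id = "S2")
  )), "single sample_id")
})

test_that("sample CTF is invariant to permutation and to ineligible additions", {
  set.seed(3)
  base <- do.call(rbind, lapply(1:5, function(i)
    make_variant(pos = i, allele_fraction = runif(1, 0.01, 0.3),
                 gene = "TP53", chrom = "17")))
  ref <- estimate_sample_ctf(base)
  perm <- base[sample(nrow(base)), ]
  expect_equal(estimate_sample_ctf(perm), ref)
  noise <- rbind(
    base,
    make_variant(origin = "germline", allele_fraction = 0.5, pos = 100),
    make_variant(chrom = "X", allele_fraction = 0.99, pos = 101, gene = "KDM6A"),
    make_variant(cna_flag = TRUE, allele_fraction = 0.99, pos = 102)
  )
  expect_equal(estimate_sample_ctf(noise), ref)
  # mean aggregate responds to the same eligibility rules
  expect_equal(estimate_sample_ctf(noise, aggregate = "mean"),
               maf_to_ctf(mean(base$allele_fraction)))
})

test_that("KRAS status requires a somatic nonsynonymous KRAS call", {
  expect_equal(call_kras_status(make_variant(gene = "KRAS")), "mutant")
  expect_equal(call_kras_status(make_variant(gene = "TP53")), "wildtype")
  expect_equal(call_kras_status(make_variant(gene = "KRAS", origin = "germline")),
               "wildtype")
  expect_equal(call_kras_status(make_variant(gene = "KRAS", effect = "synonymous")),
               "wildtype")
  expect_equal(call_kras_status(make_variant(gene = "KRAS")[0, ]), "wildtype")
})

test_that("landscape summary reports gene frequencies and the bTMB spread", {
  v <- do.call(rbind, lapply(1:4, function(i) {
    rbind(
      if (i <= 3) make_variant(sample_id = paste0("S", i), gene = "KRAS") else
        make_variant(sample_id = paste0("S", i), gene = "TP53", chrom = "17"),
      make_variant(sample_id = paste0("S", i), gene = "SMAD4", chrom = "18",
                   effect = "nonsense", pos = 7)
    )
  }))
  land <- summarize_landscape(v)
  freq <- land$gene_frequency
  expect_equal(freq$frequency[freq$gene == "KRAS"], 0.75)
  expect_equal(freq$frequency[freq$gene == "SMAD4"], 1)
  expect_error(summarize_landscape(v[0, ]), "empty cohort")

  metrics <- data.frame(sample_id = c("a", "b", "c"),
                        btmb = c(0, 3.7, 11.2),
                        n_lof_somatic = 1, n_lof_germline = 1)
  land2 <- summarize_landscape(v, metrics = metrics)
  expect_equal(unname(land2$btmb_summary), c(0, 3.7, 11.2))
})

test_that("unknown effect classes map to 'other' with a warning", {
  v <- make_variant(effect = "splice_region")
  expect_warning(out <- validate_variants(v), "other")
  expect_equal(out$effect, "other")
})

test_that("the origin heuristic labels heterozygous and homozygous bands germline", {
  expect_equal(infer_origin(c(0.45, 0.95, 0.1, 0.7)),
               c("germline", "germline", "somatic", "somatic"))
  expect_equal(infer_origin(c(0.40, 0.60, 0.90, 0.399, 0.601)),
               c("germline", "germline", "germline", "somatic", "somatic"))
})
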