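snps <- function(keys, ref = "G", alt = "A") {
  if (!length(keys)) {
    return(data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(keys, ":", fixed = TRUE)
  data.frame(chrom = vapply(parts, `[[`, "", 1),
             pos = as.integer(vapply(parts, `[[`, "", 2)),
             ref = ref, alt = alt, stringsAsFactors = FALSE)
}

test_that("shared positions intersect by coordinate, allele-agnostically", {
  a <- snps(c("c1:5", "c1:9"))
  b <- snps(c("c1:9", "c2:1"))
  expect_equal(shared_positions(a, b)$pos, 9L)
  expect_equal(nrow(shared_positions(a, snps("c2:7"))), 0L)
  # same position, different alternate allele: still shared
  diff_alt <- snps("c1:9", ref = "G", alt = "C")
  expect_equal(shared_positions(a, diff_alt)$pos, 9L)
})

test_that("shared_positions is symmetric", {
  set.seed(6)
  for (i in 1:10) {
    a <- snps(paste0("c1:", sample(50, 20)))
    b <- snps(paste0("c1:", sample(50, 20)))
    expect_equal(shared_positions(a, b), shared_positions(b, a))
  }
})

man3 <- data.frame(
  line_id = c("10-2", "10-3", "10-d", "12-2", "dhr2-1"),
  lineage_id = c("L10", "L10", "L10", "L12", "Ldhr2"),
  role = c("wt_sibling", "het_sibling", "mutant_pool", "unrelated",
           "unrelated"),
  pool_size = 1L, target_depth = 30, stringsAsFactors = FALSE)

test_that("subtraction removes cross-lineage hits, keeps within-lineage ones", {
  sets <- list(`10-d` = snps(c("c1:10", "c1:20", "c1:30")),
               `10-2` = snps("c1:20"),
               `10-3` = snps(character(0)),
               `12-2` = snps("c1:10"),
               `dhr2-1` = snps("c2:50"))
  u <- subtract_other_lineages("10-d", man3, sets)
  # c1:10 shared with lineage 12 goes; c1:20 shared only within the
  # pedigree stays
  expect_equal(u$pos, c(20L, 30L))
  expect_error(subtract_other_lineages("nope", man3, sets),
               "absent from manifest")
  # no other lineages: identity
  solo <- man3[man3$lineage_id == "L10", ]
  expect_equal(subtract_other_lineages("10-d", solo, sets),
               sets[["10-d"]])
})

test_that("subtraction partitions each input set", {
  set.seed(31)
  for (i in 1:5) {
    sets <- list(
      `10-d` = snps(paste0("c1:", sample(100, 30))),
      `10-2` = snps(paste0("c1:", sample(100, 20))),
      `10-3` = snps(paste0("c1:", sample(100, 10))),
      `12-2` = snps(paste0("c1:", sample(100, 25))),
      `dhr2-1` = snps(paste0("c1:", sample(100, 25))))
    input <- sets[["10-d"]]
    u <- subtract_other_lineages("10-d", man3, sets)
    other <- unique(c(paste("c1", sets[["12-2"]]$pos),
                      paste("c1", sets[["dhr2-1"]]$pos)))
    removed <- input[paste(input$chrom, input$pos) %in% other, ]
    expect_equal(nrow(u) + nrow(removed), nrow(input))
    expect_length(intersect(paste(u$chrom, u$pos),
                            paste(removed$chrom, removed$pos)), 0)
  }
})

test_that("venn regions match brute-force membership enumeration", {
  ident <- snps(paste0("c1:", 1:5))
  v <- venn_counts(list(A = ident, B = ident, C = ident))
  expect_equal(v$count[v$region == "A & B & C"], 5L)
  expect_equal(sum(v$count), 5L)

  disj <- venn_counts(list(A = snps("c1:1"), B = snps("c1:2"),
                           C = snps(c("c1:3", "c1:4"))))
  expect_equal(disj$count, c(1L, 1L, 2L, 0L, 0L, 0L, 0L))

  set.seed(17)
  for (i in 1:5) {
    s <- lapply(1:3, function(j) snps(paste0("c1:", sample(30, 12))))
    names(s) <- c("A", "B", "C")
    v <- venn_counts(s)
    u <- unique(unlist(lapply(s, function(x) x$pos)))
    # brute force: classify every union member by membership pattern
    pat <- vapply(u, function(p) {
      paste0(as.integer(c(p %in% s$A$pos, p %in% s$B$pos,
                          p %in% s$C$pos)), collapse = "")
    }, character(1))
    want <- c(`100` = "A only", `010` = "B only", `001` = "C only",
              `110` = "A & B", `101` = "A & C", `011` = "B & C",
              `111` = "A & B & C")
    brute <- table(factor(want[pat], levels = want))
    expect_equal(v$count, as.integer(brute[v$region]))
    expect_equal(sum(v$count), length(u))
  }
})

test_that("spectrum fraction handles pure, mixed and empty sets", {
  expect_equal(spectrum_fraction(snps(c("c1:1", "c1:2"))), 1.0)
  mixed <- rbind(snps("c1:1", ref = "G", alt = "A"),
                 snps("c1:2", ref = "A", alt = "G"))
  expect_equal(spectrum_fraction(mixed), 0.5)
  expect_true(is.na(spectrum_fraction(mixed[0, ])))
})

test_that("percent-unique follows printed-table rounding", {
  expect_equal(unique_percent(8168, 9278), 88.0)
  expect_equal(unique_percent(2084, 3845), 54.2)
  expect_equal(unique_percent(5, 5), 100.0)
  expect_true(is.na(unique_percent(0, 0)))
})

test_that("unique_summary tabulates totals, uniques and a Total row", {
  sets <- list(`10-d` = snps(paste0("c1:", 1:10)),
               `10-2` = snps(paste0("c1:", 5:12)),
               `10-3` = snps(paste0("c1:", 20:24)),
               `12-2` = snps(paste0("c1:", c(1, 2, 30))),
               `dhr2-1` = snps(paste0("c1:", c(12, 40))))
  tab <- unique_summary(man3, sets)
  expect_equal(tab$total[tab$line_id == "Total"],
               sum(tab$total[tab$line_id != "Total"]))
  d <- tab[tab$line_id == "10-d", ]
  expect_equal(d$total, 10)
  expect_equal(d$unique, 8)   # positions 1 and 2 are in lineage 12
  expect_equal(d$pct_unique, 80.0)
  expect_true(all(diff(match(c("10-2", "10-3", "10-d"),
                             tab$line_id)) > 0))
})

test_that("on simulation, subtraction removes shared artifacts, keeps EMS", {
  rep <- demo_report()
  sim <- demo_sim()
  man <- sim$manifest
  sets <- rep$survivor_sets
  lineage_of <- stats::setNames(man$lineage_id, man$line_id)
  ep_keys <- paste(sim$truth$error_prone_sites$chrom,
                   sim$truth$error_prone_sites$pos)
  # which error-prone sites were called (post-cascade) in >= 2 lineages
  called_in <- vapply(ep_keys, function(k) {
    length(unique(lineage_of[names(sets)[vapply(sets, function(s)
      k %in% paste(s$chrom, s$pos), logical(1))]]))
  }, numeric(1))
  multi <- ep_keys[called_in >= 2]
  if (length(multi)) {
    u_all <- unlist(lapply(man$line_id, function(ln) {
      u <- subtract_other_lineages(ln, man, sets)
      paste(u$chrom, u$pos)
    }))
    expect_gte(mean(!multi %in% u_all), 0.95)
  }
  # focal-lineage EMS mutations survive subtraction
  focal <- sim$truth$induced_mutations[
    sim$truth$induced_mutations$lineage == "L10", ]
  fkeys <- paste(focal$chrom, focal$pos)
  for (ln in c("10-2", "10-3", "10-d")) {
    s <- sets[[ln]]
    u <- subtract_other_lineages(ln, man, sets)
    present <- intersect(paste(s$chrom, s$pos), fkeys)
    if (length(present)) {
      expect_gte(mean(present %in% paste(u$chrom, u$pos)), 0.99)
    }
  }
})
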