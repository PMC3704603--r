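# Identifier arithmetic, incremental assignment, merge/split lifecycle,
# decimal partitions, compliance flags, and event-log replay.

test_that("URI incrementing follows the stated scheme", {
  expect_equal(next_uri(NULL), "BOLD:AAA0001")
  expect_equal(next_uri("BOLD:AAA0002"), "BOLD:AAA0003")
  expect_equal(next_uri("BOLD:AAA9999"), "BOLD:AAB0000")
  expect_equal(next_uri("BOLD:AAZ9999"), "BOLD:ABA0000")
  expect_equal(next_uri("BOLD:AZZ9999"), "BOLD:BAA0000")
  expect_error(next_uri("BOLD:ZZZ9999"), "exhausted")
  expect_error(next_uri("BOLD:AB12345"), "invalid")
})

# fixtures: three separated founders plus satellites; base2 sits ~4% from
# base1 (a new BIN, but close enough that a midpoint record can bridge)
reg_fixture <- function() {
  base1 <- make_coding_seq(658, 201)
  base2 <- substitute_bases(base1, 1:26)     # ~4.0% from base1
  base3 <- substitute_bases(base1, 300:345)  # ~7% from base1
  list(base1 = base1, base2 = base2, base3 = base3,
       near1 = substitute_bases(base1, 650),
       mid12 = substitute_bases(base1, 1:13)) # ~2% from base1 and base2
}

test_that("assignment applies the founder and join rules", {
  fx <- reg_fixture()
  reg <- bin_registry()
  r1 <- registry_assign(reg, seq_records("s1", fx$base1))
  expect_equal(r1$uri, "BOLD:AAA0001")
  r2 <- registry_assign(r1$registry, seq_records("s2", fx$base2))
  expect_equal(r2$uri, "BOLD:AAA0002")   # > 4.4% from everything: FOUND
  r3 <- registry_assign(r2$registry, seq_records("s3", fx$near1))
  expect_equal(r3$uri, "BOLD:AAA0001")   # joins its near neighbour
  expect_setequal(r3$registry$entries[["BOLD:AAA0001"]]$members,
                  c("s1", "s3"))
  expect_error(registry_assign(r3$registry, seq_records("s1", fx$base1)),
               "already registered")
})

test_that("a bridging record merges BINs, synonymizing the newer URI", {
  fx <- reg_fixture()
  reg <- bin_registry()
  reg <- registry_assign(reg, seq_records("s1", fx$base1))$registry
  reg <- registry_assign(reg, seq_records("s2", fx$base2))$registry
  res <- registry_assign(reg, seq_records("bridge", fx$mid12))
  # bridge links both at ~2%: the BINs merge and the older URI survives
  expect_equal(res$uri, "BOLD:AAA0001")
  reg <- res$registry
  expect_true("MERGE" %in% reg$events$event)
  expect_equal(reg$entries[["BOLD:AAA0002"]]$status, "SYNONYMIZED")
  expect_equal(registry_resolve(reg, "BOLD:AAA0002"), "BOLD:AAA0001")
  # the bridging record stays with the founding BIN through any
  # subsequent refinement of the collapsed unit
  part <- registry_partition(reg)
  expect_equal(unname(unclass(part)[["bridge"]]), "BOLD:AAA0001")
  expect_equal(unname(unclass(part)[["s1"]]), "BOLD:AAA0001")
})

test_that("merge orders by creation and resolution chains transitively", {
  fx <- reg_fixture()
  reg <- bin_registry()
  for (nm in c("base1", "base2", "base3"))
    reg <- registry_assign(reg, seq_records(nm, fx[[nm]]))$registry
  reg <- registry_merge(reg, "BOLD:AAA0003", "BOLD:AAA0001")
  expect_equal(reg$entries[["BOLD:AAA0003"]]$status, "SYNONYMIZED")
  expect_equal(registry_resolve(reg, "BOLD:AAA0003"), "BOLD:AAA0001")
  reg <- registry_merge(reg, "BOLD:AAA0001", "BOLD:AAA0002")
  expect_equal(registry_resolve(reg, "BOLD:AAA0002"), "BOLD:AAA0001")
  expect_equal(registry_resolve(reg, "BOLD:AAA0003"), "BOLD:AAA0001")
  expect_error(registry_merge(reg, "BOLD:AAA0001", "BOLD:AAA0002"),
               "synonymized")
})

test_that("splits retain the founder's URI and record MOVE events", {
  fx <- reg_fixture()
  reg <- bin_registry()
  ids <- sprintf("m%d", 1:6)
  seqs <- c(fx$base1, substitute_bases(fx$base1, 1),
            substitute_bases(fx$base1, 2), substitute_bases(fx$base1, 3),
            substitute_bases(fx$base1, 4), substitute_bases(fx$base1, 5))
  for (i in 1:6) reg <- registry_assign(reg, seq_records(ids[i], seqs[i]))$registry
  expect_equal(n_clusters(registry_partition(reg)), 1L)
  reg2 <- registry_split(reg, "BOLD:AAA0001",
                         list(c("m1", "m2", "m3", "m4"), c("m5", "m6")))
  expect_setequal(reg2$entries[["BOLD:AAA0001"]]$members,
                  c("m1", "m2", "m3", "m4"))
  expect_setequal(reg2$entries[["BOLD:AAA0002"]]$members, c("m5", "m6"))
  expect_true("MOVE" %in% reg2$events$event)
  expect_error(registry_split(reg, "BOLD:AAA0001",
                              list(c("m1", "m2"), c("m3"))),
               "cover")
  expect_error(registry_split(reg, "BOLD:AAA0001",
                              list(c("m2", "m3"), c("m1", "m4", "m5", "m6"))[1:1]),
               "two groups")

  # split then re-merge: original URI active, new one synonymized
  reg3 <- registry_merge(reg2, "BOLD:AAA0001", "BOLD:AAA0002")
  expect_equal(registry_resolve(reg3, "BOLD:AAA0002"), "BOLD:AAA0001")
  expect_equal(reg3$entries[["BOLD:AAA0001"]]$status, "ACTIVE")
})

test_that("incremental assignment triggers refinement splits", {
  # two haplotype clouds 1.5% apart arriving one by one: linked by SLC,
  # separated again once refinement sees >= 3 varying members
  base <- make_coding_seq(658, 202)
  far <- substitute_bases(base, seq(1, 59, by = 6))  # ~1.5% away
  cloud1 <- c(base, substitute_bases(base, 600), substitute_bases(base, 601))
  cloud2 <- c(far, substitute_bases(far, 610), substitute_bases(far, 611))
  reg <- bin_registry()
  uris <- character()
  for (i in 1:3) {
    res <- registry_assign(reg, seq_records(paste0("a", i), cloud1[i]))
    reg <- res$registry
  }
  for (i in 1:3) {
    res <- registry_assign(reg, seq_records(paste0("b", i), cloud2[i]))
    reg <- res$registry
  }
  part <- registry_partition(reg)
  expect_equal(n_clusters(part), 2L)
  expect_equal(length(unique(unclass(part)[c("a1", "a2", "a3")])), 1L)
  expect_equal(length(unique(unclass(part)[c("b1", "b2", "b3")])), 1L)
  # the founder kept the original URI through any split
  expect_equal(unname(unclass(part)[["a1"]]), "BOLD:AAA0001")
})

test_that("decimal partitions label subgroups and validate coverage", {
  base <- make_coding_seq(658, 203)
  alt <- substitute_bases(base, 200)
  state_a <- substr(base, 200, 200)
  state_b <- substr(alt, 200, 200)
  reg <- bin_registry()
  reg <- registry_assign(reg, seq_records("t1", base))$registry
  reg <- registry_assign(reg, seq_records("t2", base))$registry
  reg <- registry_assign(reg, seq_records("t3", alt))$registry
  specs <- list(list(list(pos = 200, state = state_a)),
                list(list(pos = 200, state = state_b)))
  reg <- registry_decimal_partition(reg, "BOLD:AAA0001", specs)
  expect_setequal(registry_members(reg, "BOLD:AAA0001.1"), c("t1", "t2"))
  expect_setequal(registry_members(reg, "BOLD:AAA0001.2"), "t3")
  expect_setequal(registry_members(reg, "BOLD:AAA0001"),
                  c("t1", "t2", "t3"))

  # unmatched members are an error
  bad <- list(list(list(pos = 200, state = state_a)))
  expect_error(registry_decimal_partition(reg, "BOLD:AAA0001", bad),
               "zero or multiple")
  # merge/split refuse while partitions exist
  reg2 <- registry_assign(reg, seq_records(
    "u1", substitute_bases(base, 1:40)))$registry
  expect_error(registry_merge(reg2, "BOLD:AAA0001", "BOLD:AAA0002"),
               "decimal partitions")
  expect_error(registry_split(reg2, "BOLD:AAA0001",
                              list(c("t1", "t2"), "t3")),
               "decimal partitions")
  reg3 <- registry_clear_partition(reg2, "BOLD:AAA0001")
  expect_silent(registry_split(reg3, "BOLD:AAA0001",
                               list(c("t1", "t2"), "t3")))
})

test_that("compliance flags are GREEN iff a fully compliant member exists", {
  base <- make_coding_seq(658, 204)
  reg <- bin_registry()
  reg <- registry_assign(reg, seq_records("v1", base))$registry
  reg <- registry_assign(reg, seq_records(
    "v2", substitute_bases(base, 1)))$registry
  expect_equal(reg$entries[["BOLD:AAA0001"]]$flag, "YELLOW")
  comp <- data.frame(id = c("v1", "v2"),
                     voucher = c(TRUE, TRUE),
                     country = c(TRUE, FALSE),
                     trace = c(FALSE, FALSE))
  reg <- registry_set_flag(reg, "BOLD:AAA0001", comp)
  expect_equal(reg$entries[["BOLD:AAA0001"]]$flag, "YELLOW")
  comp$trace[1] <- TRUE
  reg <- registry_set_flag(reg, "BOLD:AAA0001", comp)
  expect_equal(reg$entries[["BOLD:AAA0001"]]$flag, "GREEN")
  # a later compliant JOIN keeps the flag green (monotone recomputation)
  reg <- registry_assign(reg, seq_records(
    "v3", substitute_bases(base, 2)))$registry
  expect_equal(reg$entries[["BOLD:AAA0001"]]$flag, "GREEN")
})

test_that("event-log replay reconstructs the registry state exactly", {
  fx <- reg_fixture()
  reg <- bin_registry()
  reg <- registry_assign(reg, seq_records("s1", fx$base1))$registry
  reg <- registry_assign(reg, seq_records("s2", fx$base2))$registry
  reg <- registry_assign(reg, seq_records("s3", fx$near1))$registry
  reg <- registry_assign(reg, seq_records("bridge", fx$mid12))$registry
  reg <- registry_set_flag(reg, "BOLD:AAA0001", data.frame(
    id = "s1", voucher = TRUE, country = TRUE, trace = TRUE))
  replayed <- registry_replay(registry_events(reg), reg$seqs,
                              reg$registered_at, reg$cfg)
  expect_identical(replayed$entries, reg$entries)
  expect_identical(replayed$counter, reg$counter)
  expect_identical(replayed$last_uri, reg$last_uri)
})

test_that("a registry directory round-trips through disk", {
  fx <- reg_fixture()
  reg <- bin_registry()
  for (nm in c("base1", "base2"))
    reg <- registry_assign(reg, seq_records(nm, fx[[nm]]))$registry
  dir <- withr::local_tempdir()
  write_registry(reg, dir)
  expect_true(file.exists(file.path(dir, "events.log")))
  expect_true(file.exists(file.path(dir, "state.json")))
  back <- read_registry(dir)
  expect_identical(back$entries, reg$entries)
  expect_identical(back$seqs, reg$seqs)
  expect_identical(back$counter, reg$counter)
})

test_that("incremental assignment equals batch clustering on gapped data", {
  for (seed in 210:212) {
    sim <- simulate_barcodes(sim_spec(n_species = 8, seqs_per_species = 5,
                                      intra_max = 0.005, nn_target = 0.05,
                                      seed = seed))
    fit <- resl(sim$records)
    reg <- bin_registry()
    for (i in seq_len(nrow(sim$records)))
      reg <- registry_assign(reg, sim$records[i, , drop = FALSE])$registry
    expect_true(same_partition(registry_partition(reg), fit$otus),
                label = paste("seed", seed))
  }
})
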