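# Homogeneity QC, plain-text round trips, pipeline orchestration.

test_that("homogeneity QC flags the constructed outlier and nothing else", {
  set.seed(14)
  V <- 400
  base <- rnorm(V)
  maps <- sapply(1:10, function(i) base + rnorm(V, sd = 0.2))
  colnames(maps) <- sprintf("s%02d", 1:10)
  qc0 <- homogeneity_qc(maps)
  expect_false(any(qc0$flagged))
  maps[, 4] <- rnorm(V)   # replace one subject by independent noise
  qc1 <- homogeneity_qc(maps)
  expect_true(qc1$flagged[4])
  expect_equal(sum(qc1$flagged), 1)
  # flags invariant under common affine rescaling
  qc2 <- homogeneity_qc(3 * maps + 7)
  expect_identical(qc1$flagged, qc2$flagged)
  expect_error(homogeneity_qc(maps[, 1:2]), "at least 3")
})

test_that("all identical maps correlate perfectly and raise no flags", {
  maps <- matrix(rep(rnorm(100), 5), 100, 5)
  qc <- homogeneity_qc(maps)
  expect_true(all(abs(qc$mean_correlation - 1) < 1e-12))
  expect_false(any(qc$flagged))
})

test_that("surface maps, tables, meshes and configs round-trip through disk", {
  tmp <- withr::local_tempdir()
  x <- rnorm(50)
  f <- file.path(tmp, "map.tsv")
  write_surface_map(x, f)
  expect_equal(read_surface_map(f), x)

  co <- fixture_cohort()
  f2 <- file.path(tmp, "subjects.csv")
  write_subject_table(co$subjects, f2)
  back <- read_subject_table(f2)
  expect_equal(back$id, co$subjects$id)
  expect_equal(back$mmse, co$subjects$mmse)

  m <- fixture_mesh(2)
  d <- file.path(tmp, "mesh")
  write_mesh(m, d)
  m2 <- read_mesh(d)
  expect_equal(m2$vertices, unname(m$vertices), tolerance = 1e-12)
  expect_equal(m2$triangles, unname(m$triangles))
  expect_equal(sort(names(m2$patches)), sort(names(m$patches)))
  expect_equal(m2$patches$pons, m$patches$pons)
  expect_equal(sum(m2$area), sum(m$area), tolerance = 1e-9)

  cfg <- cohort_config(n_ehc = 5, seed = 3)
  f3 <- file.path(tmp, "cfg.json")
  write_config(cfg, f3)
  cfg2 <- read_config(f3)
  expect_equal(cfg2$coupling, cfg$coupling)
  expect_equal(cfg2$seed, cfg$seed)
})

test_that("pipeline runs end to end, caches stages, and recomputes downstream only", {
  tmp <- withr::local_tempdir()
  cfg <- pipeline_config(
    cohort = cohort_config(n_yhc = 2, n_ehc = 8, n_amci = 4, n_add = 4,
                           seed = 19),
    mesh_subdivisions = 2)
  res1 <- run_pipeline(cfg, tmp)
  outs <- c("subjects.csv", "amyloid_status.csv", "within_subject_corr.csv",
            "window_ranking.json", "window_selection.json")
  expect_true(all(file.exists(file.path(tmp, outs))))
  mans <- file.path(tmp, paste0("manifest_",
                                c("synth", "preproc", "correlate", "rank",
                                  "select"), ".json"))
  expect_true(all(file.exists(mans)))
  expect_true(all(res1$recomputed))
  hashes1 <- vapply(mans, function(f)
    jsonlite::read_json(f)$hash, character(1))

  # identical re-run is a no-op on every stage; hashes unchanged
  res2 <- run_pipeline(cfg, tmp)
  expect_false(any(res2$recomputed))
  hashes2 <- vapply(mans, function(f)
    jsonlite::read_json(f)$hash, character(1))
  expect_identical(hashes1, hashes2)

  # deleting an intermediate recomputes it and its dependents only
  unlink(file.path(tmp, "within_subject_corr.csv"))
  res3 <- run_pipeline(cfg, tmp)
  expect_false(res3$recomputed[["synth"]])
  expect_false(res3$recomputed[["preproc"]])
  expect_true(res3$recomputed[["correlate"]])
  expect_true(res3$recomputed[["rank"]])
  expect_true(res3$recomputed[["select"]])
})

test_that("pipeline config rejects unknown stages", {
  expect_error(pipeline_config(stages = c("synth", "wibble")), "wibble")
})

test_that("the command-line interface ranks a scores table", {
  tmp <- withr::local_tempdir()
  sc <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, c("a", "b", "c")))
  sc[, 1] <- sc[, 1] + 5
  fin <- file.path(tmp, "scores.csv")
  write.csv(sc, fin, row.names = FALSE)
  fout <- file.path(tmp, "rank.json")
  cli <- system.file("cli", "earlypet.R", package = "earlypet")
  out <- system2(file.path(R.home("bin"), "Rscript"),
                 c(cli, "rank", "--in", shQuote(fin), "--out", shQuote(fout)),
                 stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(fout))
  rk <- jsonlite::read_json(fout, simplifyVector = TRUE)
  expect_equal(rk$conditions[which.max(rk$mean_ranks)], "a")
})
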