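test_that("save/load round trip reproduces the cohort bit-exactly", {
  co <- generateCohort(synthConfig(nClass0 = 4L, nClass1 = 2L, nRegions = 5L,
                                   ntRange = c(16L, 20L), nSites = 2L,
                                   plantedRegions = 1:2, symptomRegion = 1L,
                                   seed = 3L))
  dir <- withr::local_tempdir()
  man <- saveCohort(co, dir)
  co2 <- loadCohort(man)
  expect_identical(subjectIds(co2), subjectIds(co))
  expect_identical(classLabels(co2), classLabels(co))
  expect_identical(siteLabels(co2), siteLabels(co))
  expect_identical(regionNames(co2), regionNames(co))
  for (i in seq_len(nSubjects(co)))
    expect_identical(getTimeseries(co2, i), unname(getTimeseries(co, i)))
  expect_identical(phenotype(co2)$score_rrb, phenotype(co)$score_rrb)
  expect_identical(phenotype(co2)$mean_fd, phenotype(co)$mean_fd)
})

test_that("loadCohort rejects broken manifests with informative errors", {
  co <- generateCohort(synthConfig(nClass0 = 3L, nClass1 = 2L, nRegions = 4L,
                                   ntRange = c(16L, 16L), nSites = 1L,
                                   plantedRegions = 1L, symptomRegion = 1L,
                                   seed = 4L))
  dir <- withr::local_tempdir()
  man <- saveCohort(co, dir)

  # missing time-series file, named after the subject
  file.rename(file.path(dir, "ts", "sub0002.tsv"),
              file.path(dir, "ts", "gone.tsv"))
  expect_error(loadCohort(man), "sub0002")
  file.rename(file.path(dir, "ts", "gone.tsv"),
              file.path(dir, "ts", "sub0002.tsv"))

  # one subject with a different region count is listed as offender
  bad <- matrix(rnorm(5 * 16), 5, 16)
  writeLines(apply(bad, 1, paste, collapse = "\t"),
             file.path(dir, "ts", "sub0003.tsv"))
  expect_error(loadCohort(man), "sub0003")

  # non-numeric cell reports file and row
  lines <- readLines(file.path(dir, "ts", "sub0003.tsv"))
  lines <- lines[1:4]
  parts <- strsplit(lines[2], "\t")[[1]]
  parts[3] <- "oops"
  lines[2] <- paste(parts, collapse = "\t")
  writeLines(lines, file.path(dir, "ts", "sub0003.tsv"))
  expect_error(loadCohort(man), "row 2")
})

test_that("z-scoring yields unit-variance rows and maps constant rows to zero", {
  m <- rbind(c(1, 2, 3), c(5, 5, 5))
  co <- Cohort(list(a = cbind(m, m, m)),
               data.frame(subject_id = "a", class_label = 0L, site = "s"))
  z <- getTimeseries(zscoreNormalize(co), 1)
  expect_equal(mean(z[1, ]), 0, tolerance = 1e-12)
  expect_equal(sd(z[1, ]), 1, tolerance = 1e-12)
  expect_identical(z[2, ], rep(0, 9))

  # independent moment recomputation on a big random matrix
  big <- matrix(rnorm(246 * 180, mean = 7, sd = 3), 246, 180)
  co2 <- Cohort(list(b = big),
                data.frame(subject_id = "b", class_label = 1L, site = "s"))
  zb <- getTimeseries(zscoreNormalize(co2), 1)
  expect_true(all(abs(rowMeans(zb)) < 1e-10))
  expect_true(all(abs(apply(zb, 1, sd) - 1) < 1e-10))

  # idempotence
  z2 <- getTimeseries(zscoreNormalize(zscoreNormalize(co2)), 1)
  expect_equal(z2, zb, tolerance = 1e-8)

  # non-finite values are refused at the data-model boundary already
  big[3, 7] <- NA
  expect_error(Cohort(list(c = big),
                      data.frame(subject_id = "c", class_label = 0L,
                                 site = "s")),
               "non-finite")
})

test_that("one-hot site encoding follows the unseen-site convention", {
  enc <- encodeSites(c("A", "B", "A"), c("A", "B"))
  expect_identical(unname(enc$matrix),
                   rbind(c(1, 0), c(0, 1), c(1, 0)))
  # out-of-vocabulary site gets the all-zero row
  enc2 <- encodeSites("C", c("A", "B"))
  expect_identical(unname(enc2$matrix), rbind(c(0, 0)))
  expect_error(encodeSites("A", c("A", "A")), "duplicate")
  expect_error(encodeSites("A", character(0)), "non-empty")

  # many-site count cross-check: row sums 1, column sums = site counts
  sites <- sample(sprintf("s%02d", 1:20), 300, replace = TRUE)
  enc3 <- encodeSites(sites, sprintf("s%02d", 1:20))
  expect_true(all(rowSums(enc3$matrix) == 1))
  expect_identical(unname(colSums(enc3$matrix)),
                   as.numeric(table(factor(sites, sprintf("s%02d", 1:20)))))
  # row sums always in {0, 1}
  encMix <- encodeSites(c(sites[1:5], "unknown"), sprintf("s%02d", 1:20))
  expect_true(all(rowSums(encMix$matrix) %in% c(0, 1)))
})

test_that("Cohort validity enforces the data-model invariants", {
  ph <- data.frame(subject_id = c("a", "b"), class_label = c(0L, 1L),
                   site = c("s", "s"))
  ts <- list(matrix(rnorm(40), 4, 10), matrix(rnorm(40), 4, 10))
  expect_s4_class(Cohort(ts, ph), "Cohort")
  # inconsistent region count across subjects
  ts2 <- list(matrix(rnorm(40), 4, 10), matrix(rnorm(50), 5, 10))
  expect_error(Cohort(ts2, ph), "regions")
  # Nt below the floor
  ts3 <- list(matrix(rnorm(28), 4, 7), matrix(rnorm(40), 4, 10))
  expect_error(Cohort(ts3, ph), "Nt")
  # duplicate ids
  ph2 <- ph; ph2$subject_id <- c("a", "a")
  expect_error(Cohort(ts, ph2), "unique")
})
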