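test_that("TIFF stacks round-trip losslessly and rescale 16-bit input", {
    dir <- withr::local_tempdir()
    set.seed(11)
    vox <- array(sample(0:255, 5 * 6 * 7, replace = TRUE), c(5, 6, 7))
    st <- makeStack(vox, zStep = 2)
    path <- file.path(dir, "stack.tif")
    writeTiffStack(st, path)
    back <- readTiffStack(path, zStep = 2, labels = expLabels(st))
    expect_identical(dim(voxels(back)), dim(vox))
    expect_equal(voxels(back), vox)
    expect_equal(depths(back), seq(0, 8, by = 2))

    ## 16-bit ceiling maps to the 8-bit ceiling under the fixed /257 rule
    p16 <- file.path(dir, "deep.tif")
    tiff::writeTIFF(list(matrix(1, 4, 4), matrix(1, 4, 4)), p16,
                    bits.per.sample = 16)
    st16 <- readTiffStack(p16, zStep = 1)
    expect_true(all(voxels(st16) == 255))
})

test_that("TIFF reader raises distinct named errors", {
    dir <- withr::local_tempdir()
    expect_error(readTiffStack(file.path(dir, "none.tif"), 1),
                 class = "clearquant_unreadable_file")
    expect_error(readTiffStack("whatever.tif", 0),
                 class = "clearquant_bad_zstep")
    bad <- file.path(dir, "notatiff.tif")
    writeLines("plain text", bad)
    expect_error(readTiffStack(bad, 1),
                 class = "clearquant_unreadable_file")
})

test_that("profile CSVs round-trip and tolerate shuffled row order", {
    dir <- withr::local_tempdir()
    p1 <- makeProfile(c(0, 10, 20), c(200, 100, 50),
                      experiment = "e1", group = "gB", specimen = "s1")
    p2 <- makeProfile(c(0, 5, 10, 15), c(255, 230, 180, 90),
                      experiment = "e2", group = "gA", specimen = "s2")
    path <- file.path(dir, "profiles.csv")
    writeProfileCsv(list(p1, p2), path)

    raw <- read.csv(path)
    expect_identical(names(raw), c("experiment_id", "group", "specimen",
                                   "region", "channel", "z_um", "intensity"))
    ## globally sorted by group then specimen: gA's experiment comes first
    expect_identical(unique(raw$group), c("gA", "gB"))

    back <- readProfileCsv(path)
    expect_length(back, 2L)
    expect_equal(depths(back[["e1"]]), depths(p1))
    expect_equal(intensities(back[["e1"]]), intensities(p1))
    expect_equal(intensities(back[["e2"]]), intensities(p2))

    ## shuffled rows parse to the same profiles
    shuf <- file.path(dir, "shuffled.csv")
    set.seed(1)
    write.csv(raw[sample(nrow(raw)), ], shuf, row.names = FALSE)
    reshuf <- readProfileCsv(shuf)
    expect_equal(depths(reshuf[["e2"]]), depths(p2))
    expect_equal(intensities(reshuf[["e2"]]), intensities(p2))
})

test_that("profile CSV reader validates schema and content", {
    dir <- withr::local_tempdir()
    base <- data.frame(experiment_id = "e", group = "g", specimen = "s",
                       region = "r", channel = "AF", z_um = c(0, 1),
                       intensity = c(10, 5))
    miss <- file.path(dir, "miss.csv")
    write.csv(base[-6L], miss, row.names = FALSE)
    expect_error(readProfileCsv(miss), class = "clearquant_missing_column")

    bad <- base; bad$intensity <- c("ten", "5")
    bpath <- file.path(dir, "bad.csv")
    write.csv(bad, bpath, row.names = FALSE)
    expect_error(readProfileCsv(bpath), class = "clearquant_bad_numeric")

    dup <- rbind(base, base[1L, ])
    dpath <- file.path(dir, "dup.csv")
    write.csv(dup, dpath, row.names = FALSE)
    expect_error(readProfileCsv(dpath), class = "clearquant_duplicate_depth")
})

test_that("maximum intensity projection obeys its display mapping and symmetries", {
    const <- makeStack(array(7, c(3, 4, 5)))
    expect_true(all(maxIntensityProjection(const) == 7))

    two <- makeStack(array(c(10, 200), c(2, 1, 1)))
    expect_equal(maxIntensityProjection(two)[1, 1], 200)

    ## a display range of (-39, 119) saturates a uniform 119 stack
    uni <- makeStack(array(119, c(2, 3, 3)))
    expect_true(all(maxIntensityProjection(uni, -39, 119) == 255))
    expect_error(maxIntensityProjection(uni, 5, 5),
                 class = "clearquant_bad_display_range")

    ## idempotent under slice duplication, invariant under slice permutation
    set.seed(4)
    vox <- array(runif(4 * 5 * 6, 0, 255), c(4, 5, 6))
    st <- makeStack(vox)
    mip <- maxIntensityProjection(st)
    expect_equal(maxIntensityProjection(makeStack(vox[c(1:4, 3), , ])), mip)
    expect_equal(maxIntensityProjection(makeStack(vox[c(3, 1, 4, 2), , ])),
                 mip)
})
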