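test_that("a toy sqlite database reads back with the expected counts", {
  ds <- toy_dataset()
  db <- withr::local_tempfile(fileext = ".sqlite")
  write_dataset(ds, db, "sqlite")
  got <- read_dataset(db, "sqlite")
  expect_equal(nrow(got$images), 3)
  expect_equal(nrow(got$objects), 6)
  expect_equal(nrow(got$relationships), 4)
  expect_equal(got$feature_names, c("Intensity_Mean", "Area"))
})

test_that("CellProfiler-style column names resolve through aliases", {
  db <- withr::local_tempfile(fileext = ".sqlite")
  write_raw_sqlite(
    db,
    image = data.frame(ImageNumber = 1:2, Metadata_Timepoint = 0:1),
    object = data.frame(ImageNumber = c(1, 2), ObjectNumber = c(1, 1),
                        Nuclei_Location_Center_X = c(5, 6),
                        Nuclei_Location_Center_Y = c(7, 8),
                        AreaShape_Area = c(40, 41)),
    relationship = data.frame(image_number1 = 1, object_number1 = 1,
                              image_number2 = 2, object_number2 = 1))
  ds <- read_dataset(db, "sqlite")
  expect_equal(ds$objects$x, c(5, 6))
  expect_equal(ds$objects$y, c(7, 8))
  expect_equal(ds$feature_names, "AreaShape_Area")
  expect_equal(nrow(ds$relationships), 1)
})

test_that("a missing centroid column raises a schema error naming it", {
  db <- withr::local_tempfile(fileext = ".sqlite")
  write_raw_sqlite(
    db,
    image = data.frame(image_index = 1),
    object = data.frame(image_index = 1, object_index = 1, y = 1, f = 2),
    relationship = data.frame(parent_image_index = integer(),
                              parent_object_index = integer(),
                              child_image_index = integer(),
                              child_object_index = integer()))
  expect_error(read_dataset(db, "sqlite"), "'x'",
               class = "trackqc_schema_error")
})

test_that("a missing table raises a schema error naming it", {
  db <- withr::local_tempfile(fileext = ".sqlite")
  con <- DBI::dbConnect(RSQLite::SQLite(), db)
  DBI::dbWriteTable(con, "image", data.frame(image_index = 1))
  DBI::dbDisconnect(con)
  expect_error(read_dataset(db, "sqlite"), "object",
               class = "trackqc_schema_error")
})

test_that("an empty relationship table yields a valid unlinked dataset", {
  images <- tibble::tibble(image_index = 1:2)
  objects <- tibble::tibble(image_index = c(1, 2), object_index = c(1, 1),
                            x = c(0, 1), y = c(0, 1))
  ds <- tracking_dataset(images, objects)
  expect_equal(nrow(ds$relationships), 0)
  expect_equal(nrow(validate_dataset(ds)), 0)
  expect_equal(nrow(graph_components(build_graph(ds))), 2)
})

test_that("every schema invariant is caught on a crafted fixture and silent on a clean one", {
  clean <- toy_dataset()
  expect_equal(nrow(validate_dataset(clean)), 0)

  raw <- function(images, objects, rel) {
    ds <- clean
    ds$images <- images %||% ds$images
    ds$objects <- objects %||% ds$objects
    ds$relationships <- rel %||% ds$relationships
    validate_dataset(ds)
  }
  `%||%` <- function(a, b) if (is.null(a)) b else a

  img_dup <- clean$images; img_dup$image_index[2] <- 1L
  expect_true("image_index_unique" %in% raw(img_dup, NULL, NULL)$rule)

  img_neg <- clean$images; img_neg$timepoint[1] <- -1L
  expect_true("timepoint_negative" %in% raw(img_neg, NULL, NULL)$rule)

  img_ord <- clean$images; img_ord$timepoint <- c(2L, 1L, 0L)
  expect_true("timepoint_order" %in% raw(img_ord, NULL, NULL)$rule)

  obj_dup <- clean$objects; obj_dup$object_index[2] <- 1L
  expect_true("object_key_unique" %in% raw(NULL, obj_dup, NULL)$rule)

  obj_nan <- clean$objects; obj_nan$x[1] <- NaN
  expect_true("centroid_not_finite" %in% raw(NULL, obj_nan, NULL)$rule)

  obj_fk <- clean$objects; obj_fk$image_index[1] <- 99L
  expect_true("object_fk" %in% raw(NULL, obj_fk, NULL)$rule)

  rel_dang <- clean$relationships; rel_dang$child_object_index[1] <- 99L
  expect_true("dangling_reference" %in% raw(NULL, NULL, rel_dang)$rule)

  rel_time <- clean$relationships
  rel_time$parent_image_index[1] <- 3L; rel_time$child_image_index[1] <- 1L
  expect_true("time_order" %in% raw(NULL, NULL, rel_time)$rule)

  rel_dup <- rbind(clean$relationships, clean$relationships[1, ])
  expect_true("duplicate_relationship" %in% raw(NULL, NULL, rel_dup)$rule)
})

test_that("write -> read round-trips exactly in both dialects, preserving feature order and gap edges", {
  images <- tibble::tibble(image_index = 1:6, timepoint = 0:5)
  objects <- tibble::tibble(
    image_index = c(1, 2, 3, 6), object_index = rep(1L, 4),
    x = c(0.123456789012345, 10, 20, 30.5), y = c(5, 6, 7, 8) / 3,
    Zeta = c(1, 2, 3, 4), Alpha = c(0.1, 0.2, 0.3, 0.4))
  rel <- tibble::tibble(parent_image_index = c(1, 2, 3),
                        parent_object_index = 1L,
                        child_image_index = c(2, 3, 6),
                        child_object_index = 1L)
  ds <- tracking_dataset(images, objects, rel)

  for (dialect in c("sqlite", "csv")) {
    path <- if (dialect == "sqlite") withr::local_tempfile(fileext = ".sqlite")
      else file.path(withr::local_tempdir(), "fx")
    write_dataset(ds, path, dialect)
    got <- read_dataset(path, dialect)
    expect_identical(tibble::as_tibble(got$objects),
                     tibble::as_tibble(ds$objects), info = dialect)
    expect_identical(got$relationships, ds$relationships, info = dialect)
    expect_equal(got$feature_names, c("Zeta", "Alpha"), info = dialect)
    # the 3-frame gap edge survives
    g <- build_graph(got)
    expect_true(3L %in% g$edges$frame_gap)
  }
})

test_that("derived relationship tables persist without touching the originals", {
  ds <- toy_dataset()
  for (dialect in c("sqlite", "csv")) {
    path <- if (dialect == "sqlite") withr::local_tempfile(fileext = ".sqlite")
      else file.path(withr::local_tempdir(), "fx")
    write_dataset(ds, path, dialect)
    ref <- read_dataset(path, dialect)
    orig_files <- if (dialect == "csv") paste0(path, "_relationships.csv") else path
    before <- lapply(orig_files, function(f) readBin(f, "raw", file.size(f)))

    edges <- ds$relationships[1:2, ]
    save_derived_relationships(ref, edges, "pruned_v1")
    expect_equal(list_derived_relationships(path, dialect), "pruned_v1")
    got <- read_derived_relationships(path, "pruned_v1", dialect)
    expect_equal(tibble::as_tibble(got), tibble::as_tibble(edges))

    # originals untouched (csv: byte-compare; sqlite: logical compare)
    if (dialect == "csv") {
      after <- lapply(orig_files, function(f) readBin(f, "raw", file.size(f)))
      expect_identical(before, after)
    } else {
      again <- read_dataset(path, dialect)
      expect_identical(again$relationships, ref$relationships)
    }

    expect_error(save_derived_relationships(ref, edges, "pruned_v1"),
                 class = "trackqc_io_error")
    expect_silent(save_derived_relationships(ref, edges, "pruned_v1",
                                             overwrite = TRUE))
  }
})

test_that("derived edges failing integrity checks are rejected", {
  ds <- toy_dataset()
  db <- withr::local_tempfile(fileext = ".sqlite")
  write_dataset(ds, db, "sqlite")
  ref <- read_dataset(db, "sqlite")
  bad <- ds$relationships
  bad$child_object_index[1] <- 99L
  expect_error(save_derived_relationships(ref, bad, "x"),
               class = "trackqc_integrity_error")
})

test_that("pruned edges of a fixture with two isolated singletons keep all original rows", {
  # two extra unlinked objects: their components span one frame each
  ds <- toy_dataset()
  objects <- rbind(ds$objects,
                   tibble::tibble(image_index = c(1L, 2L), object_index = c(9L, 9L),
                                  x = c(99, 98), y = c(99, 98),
                                  Intensity_Mean = c(0, 0), Area = c(1, 1)))
  ds2 <- tracking_dataset(ds$images, objects, ds$relationships)
  g <- build_graph(ds2)
  pr <- prune_singletons(g, 1)
  expect_equal(length(pr$removed), 2)
  edges <- graph_edges_as_relationships(pr$graph)
  # singletons have no incident edges, so all original rows remain
  expect_equal(nrow(edges), nrow(ds2$relationships))

  db <- withr::local_tempfile(fileext = ".sqlite")
  write_dataset(ds2, db, "sqlite")
  ref <- read_dataset(db, "sqlite")
  save_derived_relationships(ref, edges, "pruned")
  expect_equal(nrow(read_derived_relationships(db, "pruned", "sqlite")),
               nrow(ds2$relationships))
})

test_that("config files remap table names and aliases", {
  db <- withr::local_tempfile(fileext = ".sqlite")
  write_raw_sqlite(
    db,
    image = data.frame(idx = 1:2),
    object = data.frame(idx = c(1, 2), obj = c(1, 1), px = c(1, 2), py = c(3, 4)),
    relationship = data.frame(pi = 1, po = 1, ci = 2, co = 1),
    names = c("imgs", "objs", "rels"))
  cfg_file <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(
    table_names = list(image = "imgs", object = "objs", relationship = "rels"),
    aliases = list(
      image = list(image_index = "idx"),
      object = list(image_index = "idx", object_index = "obj",
                    x = "px", y = "py"),
      relationship = list(parent_image_index = "pi", parent_object_index = "po",
                          child_image_index = "ci", child_object_index = "co"))),
    cfg_file)
  ds <- read_dataset(db, "sqlite", config = read_config(cfg_file))
  expect_equal(nrow(ds$objects), 2)
  expect_equal(ds$objects$x, c(1, 2))
  expect_equal(nrow(ds$relationships), 1)
})
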