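# Reading, validating and writing tracking databases in the three-table
# schema (image / object / relationship), SQLite and CSV dialects.

default_table_names <- function() {
  list(image = "image", object = "object", relationship = "relationship")
}

# Column aliases, matched case-insensitively against lowercased header
# names. The first hit wins. Centroid columns additionally match any name
# *containing* "location_center_x" / "location_center_y" (the CellProfiler
# convention).
default_aliases <- function() {
  list(
    image = list(
      image_index = c("image_index", "imagenumber", "image_number"),
      group_index = c("group_index", "group_number", "groupnumber", "site", "group"),
      timepoint   = c("timepoint", "time_point", "frame", "metadata_timepoint"),
      image_path  = c("image_path", "image_filename", "filename", "path_name", "path")
    ),
    object = list(
      image_index  = c("image_index", "imagenumber", "image_number"),
      object_index = c("object_index", "objectnumber", "object_number"),
      x = c("x", "center_x", "centroid_x"),
      y = c("y", "center_y", "centroid_y")
    ),
    relationship = list(
      parent_image_index  = c("parent_image_index", "image_number1", "parent_imagenumber", "parent_image_number"),
      parent_object_index = c("parent_object_index", "object_number1", "parent_objectnumber", "parent_object_number"),
      child_image_index   = c("child_image_index", "image_number2", "imagenumber", "image_number", "image_index"),
      child_object_index  = c("child_object_index", "object_number2", "objectnumber", "object_number", "object_index")
    )
  )
}

#' Read a trackqc configuration file
#'
#' A YAML file with optional keys `table_names` (image/object/relationship)
#' and `aliases` (per-table column alias lists). Values given in the file
#' override the package defaults; everything else keeps its default.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return a config list with elements `table_names` and `aliases`.
#' @export
read_config <- function(path = NULL) {
  cfg <- list(table_names = default_table_names(), aliases = default_aliases())
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) abort_io(sprintf("config file not found: %s", path))
  user <- yaml::read_yaml(path)
  cfg$table_names <- utils::modifyList(cfg$table_names, user$table_names %||% list())
  for (tbl in names(cfg$aliases)) {
    cfg$aliases[[tbl]] <- utils::modifyList(cfg$aliases[[tbl]],
                                            user$aliases[[tbl]] %||% list())
  }
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Resolve one canonical column from a raw table, case-insensitively.
match_column <- function(raw_names, candidates, contains = NULL) {
  low <- tolower(raw_names)
  for (cand in tolower(candidates)) {
    hit <- which(low == cand)
    if (length(hit)) return(raw_names[hit[[1]]])
  }
  if (!is.null(contains)) {
    hit <- which(grepl(contains, low, fixed = TRUE))
    if (length(hit)) return(raw_names[hit[[1]]])
  }
  NA_character_
}

resolve_columns <- function(df, alias_list, required, table, contains = list()) {
  out <- list()
  for (canon in names(alias_list)) {
    hit <- match_column(names(df), alias_list[[canon]], contains[[canon]])
    if (is.na(hit) && canon %in% required) {
      abort_schema(sprintf("table '%s' is missing required column '%s'",
                           table, canon))
    }
    out[[canon]] <- hit
  }
  out
}

# Dataset constructor -----------------------------------------------------

#' Construct a tracking dataset from its three tables
#'
#' Low-level constructor used by [read_dataset()] and
#' [simulate_tracking()]. Tables must already use the canonical column
#' names (`image_index`, `object_index`, `x`, `y`,
#' `parent_/child_image_index`, ...). Feature columns are every numeric
#' object-table column that is not a key or a centroid.
#'
#' @param images tibble with `image_index`, optionally `group_index`,
#'   `timepoint`, `image_path`, plus pass-through metadata columns.
#' @param objects tibble with `image_index`, `object_index`, `x`, `y` and
#'   feature columns.
#' @param relationships tibble with the four parent/child key columns
#'   (may have zero rows).
#' @param validate error (with the first violations listed) if the tables
#'   break referential integrity.
#' @return an object of class `tracking_dataset`: a list with elements
#'   `images`, `objects`, `relationships` (tibbles) and `feature_names`.
#' @export
tracking_dataset <- function(images, objects, relationships = NULL,
                             validate = TRUE) {
  images <- tibble::as_tibble(images)
  objects <- tibble::as_tibble(objects)
  if (is.null(relationships)) {
    relationships <- tibble::tibble(parent_image_index = integer(),
                                    parent_object_index = integer(),
                                    child_image_index = integer(),
                                    child_object_index = integer())
  }
  relationships <- tibble::as_tibble(relationships)

  if (!"group_index" %in% names(images)) images$group_index <- 0L
  images$image_index <- as.integer(images$image_index)
  images$group_index <- as.integer(images$group_index)
  if (!"timepoint" %in% names(images)) {
    # 0-based rank of image_index within its group
    images <- images %>%
      dplyr::group_by(.data$group_index) %>%
      dplyr::mutate(timepoint = rank(.data$image_index) - 1L) %>%
      dplyr::ungroup()
  }
  images$timepoint <- as.integer(images$timepoint)

  for (k in c("image_index", "object_index")) {
    objects[[k]] <- as.integer(objects[[k]])
  }
  objects$x <- as.numeric(objects$x)
  objects$y <- as.numeric(objects$y)
  for (k in names(relationships)) relationships[[k]] <- as.integer(relationships[[k]])

  key_cols <- c("image_index", "object_index", "x", "y")
  other <- setdiff(names(objects), key_cols)
  numeric_ok <- vapply(objects[other], is.numeric, logical(1))
  dropped <- other[!numeric_ok]
  if (length(dropped)) {
    tq_log("WARNING", sprintf("ignoring non-numeric object column(s): %s",
                              paste(dropped, collapse = ", ")))
  }
  feature_names <- other[numeric_ok]
  objects <- objects[c(key_cols, feature_names)]
  # features are real-valued by contract; a column that happens to hold
  # whole numbers must not flip to integer across a CSV round-trip
  for (f in feature_names) objects[[f]] <- as.numeric(objects[[f]])

  ds <- structure(
    list(images = images, objects = objects, relationships = relationships,
         feature_names = feature_names),
    class = "tracking_dataset"
  )
  if (validate) {
    rep <- validate_dataset(ds)
    if (nrow(rep) > 0) {
      shown <- utils::head(rep, 10)
      abort_integrity(paste0(
        "dataset fails validation (", nrow(rep), " violation(s)); first ",
        nrow(shown), ":\n",
        paste(sprintf("  [%s] %s", shown$rule, shown$keys), collapse = "\n")))
    }
  }
  ds
}

#' @export
print.tracking_dataset <- function(x, ...) {
  cat("<tracking_dataset>\n")
  cat(sprintf("  images:        %d (groups: %d, timepoints: %d)\n",
              nrow(x$images), dplyr::n_distinct(x$images$group_index),
              dplyr::n_distinct(x$images$timepoint)))
  cat(sprintf("  objects:       %d\n", nrow(x$objects)))
  cat(sprintf("  relationships: %d\n", nrow(x$relationships)))
  cat(sprintf("  features:      %s\n",
              if (length(x$feature_names)) paste(x$feature_names, collapse = ", ")
              else "(none)"))
  invisible(x)
}

# Validation ---------------------------------------------------------------

#' Validate a tracking dataset against the schema invariants
#'
#' Checks every invariant of the three-table schema: unique image indices,
#' non-negative and strictly increasing timepoints within a group, unique
#' object keys, finite centroids, foreign keys from objects to images and
#' from relationship endpoints to objects, time-forward relationships, and
#' duplicate relationship rows. Violations are reported (and logged at
#' WARNING), never raised.
#'
#' @param ds a `tracking_dataset` (or a bare list with the same elements).
#' @return tibble with columns `rule`, `severity`, `keys`, `message`; zero
#'   rows means the dataset is valid.
#' @export
validate_dataset <- function(ds) {
  v <- list()
  add <- function(rule, keys, msg) {
    if (length(keys) == 0) return()
    v[[length(v) + 1]] <<- tibble::tibble(
      rule = rule, severity = "error", keys = as.character(keys), message = msg)
  }

  img <- ds$images
  obj <- ds$objects
  rel <- ds$relationships

  dup_img <- img$image_index[duplicated(img$image_index)]
  add("image_index_unique", unique(dup_img), "duplicate image_index")

  add("timepoint_negative", img$image_index[img$timepoint < 0],
      "timepoint < 0")

  bad_order <- img %>%
    dplyr::arrange(.data$group_index, .data$image_index) %>%
    dplyr::group_by(.data$group_index) %>%
    dplyr::filter(dplyr::row_number() > 1 &
                    .data$timepoint <= dplyr::lag(.data$timepoint)) %>%
    dplyr::ungroup()
  add("timepoint_order", bad_order$image_index,
      "timepoints not strictly increasing within group")

  okey <- node_id(obj$image_index, obj$object_index)
  add("object_key_unique", unique(okey[duplicated(okey)]),
      "duplicate (image_index, object_index)")

  add("centroid_not_finite", okey[!is.finite(obj$x) | !is.finite(obj$y)],
      "non-finite centroid")

  add("object_fk", unique(obj$image_index[!obj$image_index %in% img$image_index]),
      "object references missing image_index")

  if (nrow(rel) > 0) {
    child_k <- node_id(rel$child_image_index, rel$child_object_index)
    parent_k <- node_id(rel$parent_image_index, rel$parent_object_index)
    add("dangling_reference",
        unique(c(parent_k[!parent_k %in% okey], child_k[!child_k %in% okey])),
        "relationship endpoint not in object table")

    tp <- stats::setNames(img$timepoint, as.character(img$image_index))
    pt <- tp[as.character(rel$parent_image_index)]
    ct <- tp[as.character(rel$child_image_index)]
    bad_t <- which(!is.na(pt) & !is.na(ct) & pt >= ct)
    add("time_order",
        if (length(bad_t)) paste0(parent_k[bad_t], "->", child_k[bad_t]) else character(0),
        "parent timepoint >= child timepoint")

    rk <- paste0(parent_k, ">", child_k)
    add("duplicate_relationship", unique(rk[duplicated(rk)]),
        "duplicate relationship row")
  }

  out <- if (length(v)) dplyr::bind_rows(v) else
    tibble::tibble(rule = character(), severity = character(),
                   keys = character(), message = character())
  for (i in seq_len(nrow(out))) {
    tq_log("WARNING", sprintf("validation [%s] %s: %s",
                              out$rule[i], out$message[i], out$keys[i]))
  }
  out
}

# Reading ------------------------------------------------------------------

csv_paths <- function(prefix) {
  list(image = paste0(prefix, "_image.csv"),
       object = paste0(prefix, "_object.csv"),
       relationship = paste0(prefix, "_relationships.csv"))
}

read_raw_tables <- function(path, dialect, table_names) {
  if (dialect == "sqlite") {
    if (!file.exists(path)) abort_io(sprintf("database not found: %s", path))
    con <- DBI::dbConnect(RSQLite::SQLite(), path)
    on.exit(DBI::dbDisconnect(con))
    have <- DBI::dbListTables(con)
    raw <- list()
    for (tbl in c("image", "object", "relationship")) {
      tn <- table_names[[tbl]]
      if (!tn %in% have) abort_schema(sprintf("missing table '%s' in %s", tn, path))
      raw[[tbl]] <- tibble::as_tibble(DBI::dbReadTable(con, tn))
    }
    raw
  } else {
    paths <- csv_paths(path)
    raw <- list()
    for (tbl in names(paths)) {
      if (!file.exists(paths[[tbl]])) {
        abort_schema(sprintf("missing table '%s': file %s not found",
                             table_names[[tbl]], paths[[tbl]]))
      }
      # base parser: exact (strtod) double parsing, needed for bit-stable
      # round-trips of full-precision centroids/features
      raw[[tbl]] <- tibble::as_tibble(
        utils::read.csv(paths[[tbl]], check.names = FALSE,
                        stringsAsFactors = FALSE))
    }
    raw
  }
}

#' Read a tracking database
#'
#' Reads the three-table schema from either a SQLite file (tables `image`,
#' `object`, `relationship`; names remappable) or a CSV triplet
#' `<prefix>_image.csv`, `<prefix>_object.csv`,
#' `<prefix>_relationships.csv` where `path` is the prefix. Column names
#' are matched case-insensitively against configurable aliases; centroid
#' columns additionally match any name containing `Location_Center_X` /
#' `Location_Center_Y`. The dataset is validated on read.
#'
#' @param path SQLite file, or CSV path prefix.
#' @param dialect `"sqlite"` or `"csv"`.
#' @param table_names optional named list overriding the SQLite table names.
#' @param config a config list from [read_config()] (column aliases etc.).
#' @return a validated [tracking_dataset()]. The source location is kept in
#'   the `source` attribute so derived relationship tables can be saved
#'   back next to the originals.
#' @export
read_dataset <- function(path, dialect = c("sqlite", "csv"),
                         table_names = NULL, config = read_config()) {
  dialect <- match.arg(dialect)
  tn <- utils::modifyList(config$table_names, table_names %||% list())
  raw <- read_raw_tables(path, dialect, tn)
  al <- config$aliases

  icols <- resolve_columns(raw$image, al$image, required = "image_index",
                           table = tn$image)
  img <- raw$image
  for (canon in names(icols)) {
    if (!is.na(icols[[canon]]) && icols[[canon]] != canon) {
      names(img)[names(img) == icols[[canon]]] <- canon
    }
  }

  ocols <- resolve_columns(
    raw$object, al$object,
    required = c("image_index", "object_index", "x", "y"),
    table = tn$object,
    contains = list(x = "location_center_x", y = "location_center_y"))
  obj <- raw$object
  for (canon in names(ocols)) {
    if (ocols[[canon]] != canon) names(obj)[names(obj) == ocols[[canon]]] <- canon
  }

  rel <- raw$relationship
  if (nrow(rel) > 0 || ncol(rel) > 0) {
    rcols <- resolve_columns(rel, al$relationship,
                             required = names(al$relationship),
                             table = tn$relationship)
    for (canon in names(rcols)) {
      if (rcols[[canon]] != canon) names(rel)[names(rel) == rcols[[canon]]] <- canon
    }
    rel <- rel[names(al$relationship)]
  } else {
    rel <- NULL
  }

  ds <- tracking_dataset(img, obj, rel)
  attr(ds, "source") <- list(path = path, dialect = dialect, table_names = tn)
  ds
}

# Writing ------------------------------------------------------------------

#' Write a tracking dataset
#'
#' Writes the three tables with canonical column names, so that
#' `read_dataset()` on the result reproduces the dataset exactly (bitwise
#' for SQLite; within printed precision for CSV, which in practice is also
#' exact because the writer emits shortest round-tripping decimals).
#'
#' @param ds a `tracking_dataset`.
#' @param path SQLite file path, or CSV prefix.
#' @param dialect `"sqlite"` or `"csv"`.
#' @param overwrite replace an existing database/file set.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path, dialect = c("sqlite", "csv"),
                          overwrite = TRUE) {
  dialect <- match.arg(dialect)
  if (dialect == "sqlite") {
    if (file.exists(path)) {
      if (!overwrite) abort_io(sprintf("file exists: %s", path))
      unlink(path)
    }
    con <- DBI::dbConnect(RSQLite::SQLite(), path)
    on.exit(DBI::dbDisconnect(con))
    DBI::dbWriteTable(con, "image", as.data.frame(ds$images))
    DBI::dbWriteTable(con, "object", as.data.frame(ds$objects))
    DBI::dbWriteTable(con, "relationship", as.data.frame(ds$relationships))
  } else {
    paths <- csv_paths(path)
    dir.create(dirname(paths$image), recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(ds$images, paths$image, progress = FALSE)
    readr::write_csv(ds$objects, paths$object, progress = FALSE)
    readr::write_csv(ds$relationships, paths$relationship, progress = FALSE)
  }
  invisible(path)
}

# Derived relationship tables ----------------------------------------------

derived_table_name <- function(name) paste0("relationship__", name)

resolve_source <- function(ds, path, dialect) {
  src <- attr(ds, "source")
  path <- path %||% src$path
  dialect <- dialect %||% src$dialect
  if (is.null(path) || is.null(dialect)) {
    abort_param("dataset has no source location; pass path= and dialect=")
  }
  list(path = path, dialect = dialect)
}

#' Save a derived (e.g. pruned) relationship table alongside the original
#'
#' Stores an edited edge set under a namespaced name
#' (`relationship__<name>` as a SQLite table, or
#' `<prefix>_relationships__<name>.csv`) next to the original data, so a
#' corrected lineage graph can be retrieved across sessions. The original
#' tables are never touched.
#'
#' @param ds the dataset the edges refer to (used for integrity checks and,
#'   if `path` is omitted, for its source location).
#' @param edges tibble with the four parent/child key columns.
#' @param name derived table name (no spaces).
#' @param overwrite replace an existing derived table of the same name.
#' @param path,dialect where to store; default: where `ds` was read from.
#' @return the derived table name, invisibly.
#' @export
save_derived_relationships <- function(ds, edges, name, overwrite = FALSE,
                                       path = NULL, dialect = NULL) {
  loc <- resolve_source(ds, path, dialect)
  edges <- tibble::as_tibble(edges)[c("parent_image_index", "parent_object_index",
                                      "child_image_index", "child_object_index")]
  check <- tracking_dataset(ds$images, ds$objects, edges, validate = FALSE)
  rep <- validate_dataset(check)
  rep <- rep[rep$rule %in% c("dangling_reference", "time_order",
                             "duplicate_relationship"), ]
  if (nrow(rep) > 0) {
    abort_integrity(paste0("derived edges fail integrity checks:\n",
                           paste(sprintf("  [%s] %s", utils::head(rep$rule, 10),
                                         utils::head(rep$keys, 10)),
                                 collapse = "\n")))
  }

  if (loc$dialect == "sqlite") {
    con <- DBI::dbConnect(RSQLite::SQLite(), loc$path)
    on.exit(DBI::dbDisconnect(con))
    tn <- derived_table_name(name)
    if (tn %in% DBI::dbListTables(con) && !overwrite) {
      abort_io(sprintf("derived table '%s' already exists (use overwrite = TRUE)", name))
    }
    DBI::dbWriteTable(con, tn, as.data.frame(edges), overwrite = TRUE)
  } else {
    fp <- paste0(loc$path, "_relationships__", name, ".csv")
    if (file.exists(fp) && !overwrite) {
      abort_io(sprintf("derived table '%s' already exists (use overwrite = TRUE)", name))
    }
    readr::write_csv(edges, fp, progress = FALSE)
  }
  invisible(name)
}

#' List derived relationship tables stored with a database
#'
#' @param path SQLite file or CSV prefix.
#' @param dialect `"sqlite"` or `"csv"`.
#' @return character vector of derived table names (possibly empty).
#' @export
list_derived_relationships <- function(path, dialect = c("sqlite", "csv")) {
  dialect <- match.arg(dialect)
  if (dialect == "sqlite") {
    con <- DBI::dbConnect(RSQLite::SQLite(), path)
    on.exit(DBI::dbDisconnect(con))
    tabs <- DBI::dbListTables(con)
    sub("^relationship__", "", tabs[startsWith(tabs, "relationship__")])
  } else {
    pat <- paste0("^", basename(path), "_relationships__(.+)\\.csv$")
    files <- list.files(dirname(path), pattern = pat)
    sub(pat, "\\1", files)
  }
}

#' Read back a derived relationship table
#'
#' @inheritParams list_derived_relationships
#' @param name the name it was saved under.
#' @return tibble of relationship rows.
#' @export
read_derived_relationships <- function(path, name,
                                       dialect = c("sqlite", "csv")) {
  dialect <- match.arg(dialect)
  if (dialect == "sqlite") {
    con <- DBI::dbConnect(RSQLite::SQLite(), path)
    on.exit(DBI::dbDisconnect(con))
    tn <- derived_table_name(name)
    if (!tn %in% DBI::dbListTables(con)) {
      abort_io(sprintf("no derived table '%s' in %s", name, path))
    }
    out <- tibble::as_tibble(DBI::dbReadTable(con, tn))
  } else {
    fp <- paste0(path, "_relationships__", name, ".csv")
    if (!file.exists(fp)) abort_io(sprintf("no derived table '%s' at %s", name, fp))
    out <- tibble::as_tibble(utils::read.csv(fp, check.names = FALSE,
                                             stringsAsFactors = FALSE))
  }
  for (k in names(out)) out[[k]] <- as.integer(out[[k]])
  out
}
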