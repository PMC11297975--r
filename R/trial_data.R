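#' Construct and validate a pen table
#'
#' A pen table holds one row per pen of a two-factor feeding trial: a fish
#' size class (0 = small/autumn smolt, 1 = large/spring smolt), a dietary
#' rapeseed-oil percentage, and one or more named numeric response columns.
#' The reference design has exactly 12 pens, one per (size, oil) pair over
#' oil levels \{0, 5, 9, 14, 19, 24\}; deviations from that design are
#' flagged with a warning but not rejected.
#'
#' @param data Data frame with columns \code{size}, \code{rapeseed_oil},
#'   optionally \code{pen_id}, and numeric response columns.
#' @param units Optional named character vector of units metadata, one entry
#'   per response column.
#' @return The validated data frame with class \code{"pen_table"} and a
#'   \code{"units"} attribute.
#' @export
#' @examples
#' pt <- pen_table(data.frame(
#'   size = rep(0:1, each = 2), rapeseed_oil = rep(c(0, 24), 2),
#'   OSIPI = c(2.6, 2.9, 2.0, 2.3)
#' ))
pen_table <- function(data, units = NULL) {
  data <- as.data.frame(data)
  for (col in c("size", "rapeseed_oil")) {
    if (is.null(data[[col]])) {
      stop("pen table is missing required column '", col, "'", call. = FALSE)
    }
  }
  if (is.null(data$pen_id)) {
    data$pen_id <- paste0("pen", seq_len(nrow(data)))
  }
  if (anyDuplicated(data$pen_id)) {
    stop("pen_id values must be unique", call. = FALSE)
  }
  if (!all(data$size %in% c(0, 1))) {
    stop("size must be coded 0 (small) or 1 (large)", call. = FALSE)
  }
  if (!is.numeric(data$rapeseed_oil) ||
    any(data$rapeseed_oil < 0 | data$rapeseed_oil > 100)) {
    stop("rapeseed_oil must be a percentage in [0, 100]", call. = FALSE)
  }
  if (anyDuplicated(data[c("size", "rapeseed_oil")])) {
    warning("duplicated (size, rapeseed_oil) cells: design is replicated",
      call. = FALSE
    )
  }
  resp <- setdiff(names(data), c("pen_id", "size", "rapeseed_oil"))
  for (v in resp) {
    if (!is.numeric(data[[v]])) {
      stop("response column '", v, "' is not numeric", call. = FALSE)
    }
  }
  if (nrow(data) != 12) {
    warning("pen table has ", nrow(data),
      " rows; the reference design has 12 (one per size x oil cell)",
      call. = FALSE
    )
  }
  data <- data[c("pen_id", "size", "rapeseed_oil", resp)]
  if (!is.null(units)) {
    units <- units[intersect(names(units), resp)]
  }
  structure(data, units = units, class = c("pen_table", "data.frame"))
}

#' Read a pen table from CSV
#'
#' The CSV dialect is fixed: comma-separated, UTF-8, dot decimal separator,
#' header row required. Header names are matched case-insensitively against
#' the expected schema.
#'
#' @param path Path to the CSV file.
#' @param responses Optional character vector naming the response columns
#'   that must be present (the schema); by default all non-key columns are
#'   taken as responses.
#' @param units Optional named units vector passed to [pen_table()].
#' @return A validated [pen_table()].
#' @export
read_pen_table <- function(path, responses = NULL, units = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path,
    check.names = FALSE, fileEncoding = "UTF-8",
    colClasses = "character"
  )
  names(raw) <- trimws(names(raw))
  lower <- tolower(names(raw))
  for (key in c("size", "rapeseed_oil")) {
    hit <- which(lower == key)
    if (length(hit) == 0) {
      stop("schema error: missing column '", key, "'", call. = FALSE)
    }
    names(raw)[hit[1]] <- key
  }
  if ("pen_id" %in% lower) names(raw)[which(lower == "pen_id")[1]] <- "pen_id"
  if (!is.null(responses)) {
    for (v in responses) {
      hit <- which(lower == tolower(v))
      if (length(hit) == 0) {
        stop("schema error: missing column '", v, "'", call. = FALSE)
      }
      names(raw)[hit[1]] <- v
    }
  }
  resp <- if (is.null(responses)) {
    setdiff(names(raw), c("pen_id", "size", "rapeseed_oil"))
  } else {
    responses
  }
  for (v in c("size", "rapeseed_oil", resp)) {
    num <- suppressWarnings(as.numeric(raw[[v]]))
    bad <- which(is.na(num) & !is.na(raw[[v]]) & nzchar(raw[[v]]))
    if (length(bad) > 0) {
      stop("parse error: non-numeric value '", raw[[v]][bad[1]],
        "' in column '", v, "', row ", bad[1],
        call. = FALSE
      )
    }
    raw[[v]] <- num
  }
  pen_table(raw[c(
    intersect("pen_id", names(raw)), "size", "rapeseed_oil", resp
  )], units = units)
}

#' Write a pen table to CSV
#'
#' Inverse of [read_pen_table()]; \code{write} then \code{read} is the
#' identity on the table's content.
#'
#' @param x A [pen_table()].
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_pen_table <- function(x, path) {
  utils::write.csv(as.data.frame(x), path,
    row.names = FALSE, quote = FALSE,
    fileEncoding = "UTF-8"
  )
  invisible(path)
}

#' @export
print.pen_table <- function(x, ...) {
  cat("Pen table: ", nrow(x), " pens, ",
    length(setdiff(names(x), c("pen_id", "size", "rapeseed_oil"))),
    " response variable(s)\n",
    sep = ""
  )
  print(as.data.frame(x), ...)
  invisible(x)
}

.fixture_files <- c(
  feed_composition = "feed_composition.csv",
  feed_fatty_acids = "feed_fatty_acids.csv",
  digestibility_means = "digestibility_means.csv",
  digestibility_stats = "digestibility_stats.csv",
  organ_lipid = "organ_lipid.csv",
  organ_lipid_stats = "organ_lipid_stats.csv",
  score_lines = "score_lines.csv"
)

#' Packaged trial tables
#'
#' Read-only copies of the published trial tables: feed ingredient and
#' analyzed composition, feed fatty-acid composition, group-mean apparent
#' digestibilities with their model-selection statistics, the 12-pen organ
#' index and tissue-lipid table with its statistics row, and the published
#' first-degree steatosis score lines. Values are stored exactly as printed
#' (1-2 decimals); no back-correction toward unrounded pen means is applied.
#'
#' @param name One of \code{"feed_composition"}, \code{"feed_fatty_acids"},
#'   \code{"digestibility_means"}, \code{"digestibility_stats"},
#'   \code{"organ_lipid"}, \code{"organ_lipid_stats"}, \code{"score_lines"}.
#' @return A data frame; \code{"organ_lipid"} is returned as a
#'   [pen_table()]. Repeated calls return equal content, and mutating the
#'   returned copy does not alter the catalog.
#' @export
#' @examples
#' trial_fixture("organ_lipid")
#' subset(trial_fixture("feed_composition"), item == "Choline")
trial_fixture <- function(name) {
  if (length(name) != 1 || !name %in% names(.fixture_files)) {
    stop("unknown fixture '", name, "'; available: ",
      paste(names(.fixture_files), collapse = ", "),
      call. = FALSE
    )
  }
  path <- system.file("extdata", .fixture_files[[name]],
    package = "pentrial", mustWork = TRUE
  )
  tab <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  if (name == "organ_lipid") {
    units <- c(
      sum_dig_FA = "g/kg feed", OSIPI = "%", PI_lipid = "g/kg",
      OSIDI = "%", OSIMes = "%", Mes_lipid = "g/kg", OSILI = "%",
      LI_lipid = "g/kg"
    )
    tab <- pen_table(tab, units = units)
  }
  tab
}
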