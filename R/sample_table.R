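#' Read a sample table (deposited-data schema)
#'
#' Reads a per-sample table of coordinates, assigned cluster, soil
#' properties, terrain covariates and microbial indicators from CSV or
#' XLSX (XLSX needs the readxl package).  Headers are matched
#' case-insensitively against a synonym map covering common spellings
#' ("%TC", "percent total carbon", "MBC (ug C/g DW)", ...); unknown
#' columns are kept as extras.
#'
#' @param path CSV or XLSX file.
#' @param synonyms optional named list extending/overriding the built-in
#'   synonym map: names are canonical column names, values character
#'   vectors of accepted headers.
#' @return data frame with canonical column names (`x`, `y`, `cluster`,
#'   `moisture_gg`, `ph`, `mbc`, `mbn`, `specific_c_min`,
#'   `specific_n_min`, `tc_pct`, `tn_pct`, `elevation`, `slope`,
#'   `aspect`, `plan_curvature`, `emi_hh`, `emi_vv`, ... as present).
#' @export
read_sample_table <- function(path, synonyms = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("xlsx", "xls")) {
    if (!requireNamespace("readxl", quietly = TRUE))
      stop("reading XLSX requires the readxl package; ",
           "export the sheet to CSV instead", call. = FALSE)
    as.data.frame(readxl::read_excel(path))
  } else {
    read.csv(path, check.names = FALSE)
  }
  map <- synonym_map()
  if (!is.null(synonyms)) map[names(synonyms)] <- synonyms
  canon <- function(h) {
    hs <- simplify_header(h)
    for (nm in names(map))
      if (hs %in% vapply(c(nm, map[[nm]]), simplify_header, character(1)))
        return(nm)
    h
  }
  names(raw) <- vapply(names(raw), canon, character(1))
  mandatory <- c("x", "y", "cluster")
  miss <- setdiff(mandatory, names(raw))
  ind_present <- intersect(indicator_columns(), names(raw))
  if (length(miss) || !length(ind_present))
    stop("sample table missing mandatory column(s): ",
         paste(c(miss, if (!length(ind_present)) "<any indicator>"),
               collapse = ", "), call. = FALSE)
  raw
}

simplify_header <- function(h) gsub("[^a-z0-9]", "", tolower(h))

synonym_map <- function() list(
  x = c("easting", "easting_m", "east", "utm easting"),
  y = c("northing", "northing_m", "north", "utm northing"),
  cluster = c("assigned cluster", "cluster id", "som cluster", "group",
              "zone"),
  moisture_gg = c("moisture", "moisture content", "moisture (g/g)",
                  "gravimetric water content"),
  fw_dw_ratio = c("fw/dw", "fw dw ratio", "fresh weight to dry weight"),
  ph = c("soil ph", "pH"),
  mbc = c("mbc (ug c/g dw)", "microbial biomass carbon",
          "microbial biomass c"),
  mbn = c("mbn (ug n/g dw)", "microbial biomass nitrogen",
          "microbial biomass n"),
  specific_c_min = c("specific c mineralization", "specific cmin",
                     "specific carbon mineralization"),
  specific_n_min = c("specific n mineralization", "specific nmin",
                     "specific nitrogen mineralization"),
  tc_pct = c("%tc", "percent total carbon", "total c", "tc"),
  tn_pct = c("%tn", "percent total nitrogen", "total n", "tn"),
  eoc = c("doc", "extractable organic carbon",
          "extractable dissolved organic carbon"),
  nitrate = c("no3", "no3-n", "extractable nitrate"),
  ammonium = c("nh4", "nh4-n", "extractable ammonium", "ammonia"),
  n_min = c("n mineralization", "nmin rate", "potential n mineralization"),
  c_min = c("c mineralization", "cmin rate", "potential c mineralization"),
  elevation = c("elevation (m)", "elev", "elevation m"),
  slope = c("slope (%)", "slope pct", "slope percent"),
  aspect = c("aspect (degrees)", "slope aspect", "aspect degrees"),
  plan_curvature = c("plan curvature", "planar curvature", "plan curv"),
  emi_hh = c("h-h emi", "hh emi", "emi hh", "h-h emi (ms/m)",
             "horizontal emi", "horizontal-polarization emi"),
  emi_vv = c("v-v emi", "vv emi", "emi vv", "v-v emi (ms/m)",
             "vertical emi", "vertical-polarization emi"))

#' Write a sample table to CSV
#'
#' @param st sample table (data frame).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sample_table <- function(st, path) {
  write.csv(st, path, row.names = FALSE)
  invisible(path)
}

#' Validate a sample table against an expected design
#'
#' Checks cluster ids and, optionally, the expected per-cluster count
#' (e.g. 12 sites in each of 3 clusters for a 36-site design).
#'
#' @param st sample table.
#' @param per_cluster expected members per cluster, or `NULL` to skip.
#' @return `st` invisibly; errors describe any violation.
#' @export
validate_sample_table <- function(st, per_cluster = NULL) {
  stopifnot("cluster" %in% names(st))
  if (any(is.na(st$cluster)))
    stop("missing cluster ids", call. = FALSE)
  if (!is.null(per_cluster)) {
    counts <- table(st$cluster)
    if (!all(counts == per_cluster))
      stop("expected ", per_cluster, " rows per cluster, found: ",
           paste(sprintf("%s=%d", names(counts), counts), collapse = ", "),
           call. = FALSE)
  }
  invisible(st)
}
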