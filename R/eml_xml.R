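#' Serialize a metadata record to EML
#'
#' Writes the record as a well-formed XML document using the EML 2.1.1
#' element vocabulary: `dataset/title`, `creator` and `contact` with
#' `individualName`, `address` and `electronicMailAddress`, `abstract`,
#' `keywordSet`, `coverage` (temporal range and geographic bounding box),
#' `intellectualRights`, `project`, `publisher`, and a
#' `dataTable/attributeList` whose `attribute` entries carry
#' `attributeName`/`attributeDefinition`/`unit` (plus measurement type and
#' missing-value code when present). Only populated fields are emitted, and
#' [from_eml()] recovers every populated field -- the serialization is
#' lossless over the schema. Full XSD validation is deliberately not
#' performed; well-formedness plus the round-trip is the contract.
#'
#' @param md a `metadata_record`; must pass [validate_metadata()].
#' @param path optional file to write (UTF-8).
#' @return the XML document as a string (invisibly when `path` is given).
#' @export
to_eml <- function(md, path = NULL) {
  findings <- validate_metadata(md)
  if (nrow(findings) > 0) {
    stop("metadata record is incomplete or invalid:\n",
         paste0("  - ", findings$element, ": ", findings$problem,
                collapse = "\n"), call. = FALSE)
  }
  fl <- md$file_level
  el <- function(tag, value) {
    if (is.null(value) || !any(nzchar(value))) return("")
    paste0("<", tag, ">", xml_escape(value), "</", tag, ">", collapse = "")
  }
  wrap <- function(tag, inner, attrs = "") {
    inner <- paste(inner, collapse = "")
    if (!nzchar(inner)) return("")
    paste0("<", tag, attrs, ">", inner, "</", tag, ">")
  }
  person <- function(prefix) {
    g <- function(field) fl[[paste0(prefix, "_", field)]]
    paste0(
      wrap("individualName", c(el("givenName", g("first_name")),
                               el("surName", g("last_name")))),
      el("organizationName", g("organization")),
      wrap("address", c(el("deliveryPoint", g("address")),
                        el("city", g("city")),
                        el("administrativeArea", g("state")),
                        el("postalCode", g("postal_code")),
                        el("country", g("country")))),
      el("phone", g("phone")),
      el("electronicMailAddress", g("email")))
  }
  attrs_xml <- if (nrow(md$attributes) > 0) {
    wrap("attributeList", vapply(seq_len(nrow(md$attributes)), function(i) {
      at <- md$attributes[i, ]
      wrap("attribute", c(
        el("attributeName", at$parameter_name),
        el("attributeDefinition", at$description),
        el("unit", at$units),
        el("measurementType", at$measurement_type),
        el("missingValueCode", at$missing_value_code)),
        attrs = sprintf(" id=\"attr%d\"", at$column_index))
    }, character(1)))
  } else ""
  doc <- paste0(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>\n",
    "<eml:eml xmlns:eml=\"eml://ecoinformatics.org/eml-2.1.1\" ",
    "packageId=\"", xml_escape(fl$identifier %||% "unassigned"),
    "\" system=\"curatr\">",
    wrap("dataset", c(
      el("alternateIdentifier", fl$identifier),
      el("title", fl$title),
      wrap("creator", person("creator")),
      el("pubDate", fl$today_date),
      wrap("abstract", el("para", fl$abstract)),
      wrap("keywordSet", c(
        el("keyword", fl$keywords),
        el("keywordThesaurus", fl$keyword_thesaurus))),
      wrap("additionalInfo", el("para", fl$citation)),
      wrap("intellectualRights", el("para", fl$intellectual_rights)),
      wrap("coverage", c(
        wrap("geographicCoverage", c(
          el("geographicDescription", fl$geographic_description),
          wrap("boundingCoordinates", c(
            el("westBoundingCoordinate", fl$west_bounding),
            el("eastBoundingCoordinate", fl$east_bounding),
            el("northBoundingCoordinate", fl$north_bounding),
            el("southBoundingCoordinate", fl$south_bounding))))),
        wrap("temporalCoverage", wrap("rangeOfDates", c(
          wrap("beginDate", el("calendarDate", fl$temporal_begin)),
          wrap("endDate", el("calendarDate", fl$temporal_end))))))),
      wrap("contact", person("contact")),
      wrap("publisher", el("organizationName", fl$publisher)),
      wrap("project", c(
        el("title", fl$project_title),
        wrap("abstract", el("para", fl$project_description)),
        wrap("personnel", c(
          wrap("individualName", el("surName", fl$project_personnel)),
          el("role", fl$project_personnel_role))))),
      wrap("dataTable", c(
        el("entityName", fl$data_table_name),
        el("entityDescription", fl$data_table_description),
        attrs_xml)))),
    "</eml:eml>")
  # ensure well-formedness before handing it out
  xml2::read_xml(doc)
  if (!is.null(path)) {
    writeLines(doc, path, useBytes = TRUE)
    return(invisible(doc))
  }
  doc
}

#' @rdname to_eml
#' @param x an EML string, file path or `xml_document`.
#' @export
from_eml <- function(x) {
  doc <- if (inherits(x, "xml_document")) x else xml2::read_xml(x)
  txt <- function(path) {
    node <- xp1(doc, path)
    if (inherits(node, "xml_missing")) return(NULL)
    v <- xml2::xml_text(node)
    if (nzchar(v)) v else NULL
  }
  txts <- function(path) {
    nodes <- xp(doc, path)
    if (length(nodes) == 0) return(NULL)
    xml2::xml_text(nodes)
  }
  ds <- paste0("//", lname("dataset"), "/")
  person_path <- function(who) paste0(ds, lname(who), "/")
  person_fields <- function(who) {
    p <- person_path(who)
    list(
      first_name = txt(paste0(p, lname("individualName"), "/", lname("givenName"))),
      last_name = txt(paste0(p, lname("individualName"), "/", lname("surName"))),
      organization = txt(paste0(p, lname("organizationName"))),
      address = txt(paste0(p, lname("address"), "/", lname("deliveryPoint"))),
      city = txt(paste0(p, lname("address"), "/", lname("city"))),
      state = txt(paste0(p, lname("address"), "/", lname("administrativeArea"))),
      postal_code = txt(paste0(p, lname("address"), "/", lname("postalCode"))),
      country = txt(paste0(p, lname("address"), "/", lname("country"))),
      phone = txt(paste0(p, lname("phone"))),
      email = txt(paste0(p, lname("electronicMailAddress"))))
  }
  creator <- person_fields("creator")
  contact <- person_fields("contact")
  cov <- paste0(ds, lname("coverage"), "/")
  geo <- paste0(cov, lname("geographicCoverage"), "/")
  bc <- paste0(geo, lname("boundingCoordinates"), "/")
  tc <- paste0(cov, lname("temporalCoverage"), "/", lname("rangeOfDates"), "/")
  proj <- paste0(ds, lname("project"), "/")
  dt <- paste0(ds, lname("dataTable"), "/")
  fl <- list(
    today_date = txt(paste0(ds, lname("pubDate"))),
    title = txt(paste0(ds, lname("title"))),
    abstract = txt(paste0(ds, lname("abstract"), "/", lname("para"))),
    keywords = txts(paste0(ds, lname("keywordSet"), "/", lname("keyword"))),
    keyword_thesaurus = txt(paste0(ds, lname("keywordSet"), "/",
                                   lname("keywordThesaurus"))),
    identifier = txt(paste0(ds, lname("alternateIdentifier"))),
    citation = txt(paste0(ds, lname("additionalInfo"), "/", lname("para"))),
    temporal_begin = txt(paste0(tc, lname("beginDate"), "/", lname("calendarDate"))),
    temporal_end = txt(paste0(tc, lname("endDate"), "/", lname("calendarDate"))),
    geographic_description = txt(paste0(geo, lname("geographicDescription"))),
    west_bounding = txt(paste0(bc, lname("westBoundingCoordinate"))),
    east_bounding = txt(paste0(bc, lname("eastBoundingCoordinate"))),
    north_bounding = txt(paste0(bc, lname("northBoundingCoordinate"))),
    south_bounding = txt(paste0(bc, lname("southBoundingCoordinate"))),
    intellectual_rights = txt(paste0(ds, lname("intellectualRights"), "/", lname("para"))),
    project_title = txt(paste0(proj, lname("title"))),
    project_description = txt(paste0(proj, lname("abstract"), "/", lname("para"))),
    project_personnel = txt(paste0(proj, lname("personnel"), "/",
                                   lname("individualName"), "/", lname("surName"))),
    project_personnel_role = txt(paste0(proj, lname("personnel"), "/", lname("role"))),
    publisher = txt(paste0(ds, lname("publisher"), "/", lname("organizationName"))),
    data_table_name = txt(paste0(dt, lname("entityName"))),
    data_table_description = txt(paste0(dt, lname("entityDescription"))))
  for (field in names(creator)) {
    fl[[paste0("creator_", field)]] <- creator[[field]]
    fl[[paste0("contact_", field)]] <- contact[[field]]
  }
  attr_nodes <- xp(doc, paste0(dt, lname("attributeList"), "/", lname("attribute")))
  attributes <- if (length(attr_nodes) > 0) {
    do.call(rbind, lapply(seq_along(attr_nodes), function(i) {
      at <- attr_nodes[[i]]
      g <- function(tag) {
        n <- xp1(at, lname(tag))
        if (inherits(n, "xml_missing")) "" else xml2::xml_text(n)
      }
      data.frame(parameter_name = g("attributeName"),
                 description = g("attributeDefinition"),
                 units = g("unit"),
                 measurement_type = g("measurementType"),
                 missing_value_code = g("missingValueCode"),
                 column_index = i, stringsAsFactors = FALSE)
    }))
  } else NULL
  new_metadata(Filter(Negate(is.null), fl), attributes)
}
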