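#' The 47-element metadata schema
#'
#' A deliberately small subset of the Ecological Metadata Language (EML)
#' vocabulary, chosen to keep the barrier to documenting a dataset low: 42
#' file-level elements in three groups (basic information, personnel,
#' dataset) plus 5 attribute-level elements describing the columns of a data
#' table -- 47 in all, of which exactly 7 are required. Completeness of a
#' metadata record is precisely the predicate "all 7 required elements are
#' non-empty"; everything else is optional enrichment.
#'
#' @return a data.frame with one row per element: `id` (stable snake_case
#'   key), `name` (display name), `group` (`"basic"`, `"personnel"`,
#'   `"dataset"`, `"attribute"`) and `required`.
#' @examples
#' nrow(schema_elements())            # 47
#' sum(schema_elements()$required)    # 7
#' @export
schema_elements <- function() {
  e <- function(id, name, group, required = FALSE) {
    data.frame(id = id, name = name, group = group, required = required,
               stringsAsFactors = FALSE)
  }
  rbind(
    e("today_date", "Today's date", "basic", TRUE),
    e("title", "Title of dataset", "basic", TRUE),
    e("abstract", "Abstract", "basic", TRUE),
    e("keywords", "Keyword(s)", "basic", TRUE),
    e("keyword_thesaurus", "Keyword thesaurus used", "basic"),
    e("identifier", "Identifier", "basic"),
    e("citation", "Formatted citation", "basic"),
    e("creator_first_name", "Creator: First name", "personnel", TRUE),
    e("creator_last_name", "Creator: Last name", "personnel", TRUE),
    e("creator_organization", "Creator: Organization", "personnel"),
    e("creator_address", "Creator: Address", "personnel"),
    e("creator_city", "Creator: City", "personnel"),
    e("creator_state", "Creator: State/province", "personnel"),
    e("creator_postal_code", "Creator: Postal code", "personnel"),
    e("creator_country", "Creator: Country", "personnel"),
    e("creator_phone", "Creator: Phone", "personnel"),
    e("creator_email", "Creator: Email", "personnel", TRUE),
    e("contact_first_name", "Data Contact Person: First name", "personnel"),
    e("contact_last_name", "Data Contact Person: Last name", "personnel"),
    e("contact_organization", "Data Contact Person: Organization", "personnel"),
    e("contact_address", "Data Contact Person: Address", "personnel"),
    e("contact_city", "Data Contact Person: City", "personnel"),
    e("contact_state", "Data Contact Person: State/province", "personnel"),
    e("contact_postal_code", "Data Contact Person: Postal code", "personnel"),
    e("contact_country", "Data Contact Person: Country", "personnel"),
    e("contact_phone", "Data Contact Person: Phone", "personnel"),
    e("contact_email", "Data Contact Person: Email", "personnel"),
    e("temporal_begin", "Temporal coverage: Beginning date", "dataset"),
    e("temporal_end", "Temporal coverage: Ending date", "dataset"),
    e("geographic_description", "Geographic coverage: Description", "dataset"),
    e("west_bounding", "West bounding coordinate", "dataset"),
    e("east_bounding", "East bounding coordinate", "dataset"),
    e("north_bounding", "North bounding coordinate", "dataset"),
    e("south_bounding", "South bounding coordinate", "dataset"),
    e("intellectual_rights", "Intellectual rights", "dataset"),
    e("project_title", "Project title", "dataset"),
    e("project_description", "Project description", "dataset"),
    e("project_personnel", "Project personnel", "dataset"),
    e("project_personnel_role", "Project personnel role", "dataset"),
    e("publisher", "Data Publisher: repository name", "dataset"),
    e("data_table_name", "Data table name", "dataset"),
    e("data_table_description", "Data table description", "dataset"),
    e("attribute_name", "Parameter name", "attribute"),
    e("attribute_definition", "Parameter description", "attribute"),
    e("attribute_unit", "Parameter units", "attribute"),
    e("attribute_measurement_type", "Parameter measurement type", "attribute"),
    e("attribute_missing_code", "Parameter missing value code", "attribute")
  )
}

file_level_ids <- function() {
  s <- schema_elements()
  s$id[s$group != "attribute"]
}

required_ids <- function() {
  s <- schema_elements()
  s$id[s$required]
}
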