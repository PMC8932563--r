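# In-code fixtures: a small two-colony survey directory in tempdir.

write_fixture_dir <- function(dir = tempfile("surveys")) {
  dir.create(dir)
  writeLines(c(
    "colony_id,name,state,region,latitude,longitude,area_ha,height_m",
    "AA,Alpha Rocks,Victoria,Central Bass Strait,-38.5,145.2,8,10",
    "BB,Beta Island,Tasmania,East Australian Current,-40.6,148.3,4,7"),
    file.path(dir, "colonies.csv"))
  writeLines(c(
    "colony_id,date,subarea_id,marked_available,total_resighted,marked_resighted,dead_marked,dead_clear",
    "AA,2018-01-10,S1,100,150,50,0,2",
    "AA,2018-01-10,S2,80,100,40,5,0",
    "AA,2017-12-16,S1,60,80,30,0,0"),
    file.path(dir, "cmr_surveys.csv"))
  writeLines(c(
    "colony_id,date,observer_id,count,method",
    "BB,2018-01-08,1,100,direct_count",
    "BB,2018-01-08,2,110,direct_count",
    "BB,2018-01-08,3,120,direct_count"),
    file.path(dir, "count_surveys.csv"))
  dir
}

# numeric percent-change labels from the published census table
parse_change_label <- function(x) {
  suppressWarnings(as.numeric(sub("^\\+", "", x)))
}
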