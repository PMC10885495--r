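# A complete, audit-clean quarterly record for a well-run facility.
# Chosen so that several indicator scores are known by hand:
# H1=5 (800 bags/day needs 300 m2, has 350), H3=5 (5 consoles for 180
# beds), P1=2 (training ratio exactly 1), P2=5 (all pharmacists), P3=4,
# W1=10 (all four drug classes), W2=3 (800 vs reference 1500), W3=3,
# W4=5, W5=5, W6=5 (temporary rate 33%), W7=6 (450 reviewed), W8=5,
# W9=5, I1=5, I2=5, I3=3, N1=8, N2=2 (5 traceable kinds / 5 consoles).
full_record <- function() {
  c(A01 = "Test Hospital", A02 = "1 Test Road", A03 = "Rep",
    A04 = "Pharm Director", A05 = "87100001", A06 = "Reporter",
    A07 = "pharmacist", A08 = "tertiary A", A09 = "650001",
    A10 = "Director", A11 = "13800000001", A12 = "2015-01-01",
    B01 = "350", B02 = "600", B03 = "15", B04 = "180", B05 = "2",
    B06 = "4", B07 = "6", B08 = "2", B09 = "40", B10 = "180",
    B11 = "180", B12 = "1",
    C01 = "3", C02 = "2", C03 = "4", C04 = "180", C05 = "bachelor",
    C06 = "0", C07 = "3", C08 = "1", C09 = "supervising pharmacist",
    C10 = "10",
    D01 = "70000", D02 = "20000", D03 = "15000", D04 = "450",
    D05 = "600", D06 = "300", D07 = "returning", D08 = "50",
    D09 = "30000", D10 = "750", D11 = "25000", D12 = "7000",
    D13 = "85", D14 = "38500", D15 = "200", D16 = "0.78",
    D17 = "270", D18 = "40", D19 = "30",
    E01 = "13", E02 = "96", E03 = "98", E04 = "1", E05 = "1",
    E06 = "1", E07 = "97", E08 = "95", E09 = "12", E10 = "13",
    E11 = "ethanol, ultraviolet",
    F01 = paste("dispensing scanner, dispensing robot, sorting machine,",
                "infusion labeling system, vertical flow clean bench"),
    F02 = "TRUE", F03 = "TRUE")
}

full_submission <- function(overrides = NULL, ...) {
  rec <- full_record()
  if (!is.null(overrides)) rec[names(overrides)] <- overrides
  parse_submission(rec, facility_id = "T01", year = 2020, quarter = 1, ...)
}

# Minimal submission carrying only the items/metrics an indicator needs,
# on top of the full fixture.
sub_with <- function(...) full_submission(overrides = c(...))
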