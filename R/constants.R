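# Monoisotopic reference mass shifts (Da).
# Cit / deamidation: O replaces NH (15.994915 - 14.003074 - 1.007825).
# hCit / carbamylation: +HNCO (1.007825 + 12 + 14.003074 + 15.994915).
DELTA_CIT <- 0.98402
DELTA_CARBAMYL <- 43.00581

# iTRAQ 8-plex reporter channels; the study's channel -> group map lives
# in reporter_design(): three normozoospermic (NZ) pools on 113/114/119,
# five non-NZ pools on 115/116/117/118/121.
ITRAQ_CHANNELS <- c("113", "114", "115", "116", "117", "118", "119", "121")

MOD_CLASSES <- c("Cit", "hCit", "Deamidation", "NtermCarbamyl", "Other")
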