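# Default human housekeeping genes used as negative controls.
# Replace with any one-symbol-per-line list via the controls option.
ACTB
GAPDH
B2M
HPRT1
RPL13A
RPLP0
RPL19
RPL27
RPL30
RPL37A
RPS18
RPS29
SDHA
TBP
UBC
YWHAZ
PGK1
PPIA
PPIB
GUSB
TFRC
HMBS
POLR2A
EEF1A1
EIF4A2
ATP5F1B
CYC1
UBB
RPL9
RPL24
RPS13
RPS20
PSMB2
PSMB4
RAB7A
REEP5
SNRPD3
VCP
VPS29
EMC7
GPI
CHMP2A
C1ORF43
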