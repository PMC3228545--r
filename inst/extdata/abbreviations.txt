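# Protected abbreviations for sentence splitting: a period ending one of
# these tokens never terminates a sentence. One per line; matching is
# case-insensitive and requires a non-alphanumeric character (or start of
# text) immediately before the abbreviation.
e.g.
i.e.
et al.
al.
cf.
ca.
vs.
sp.
spp.
fig.
figs.
eq.
ref.
refs.
no.
dr.
prof.
st.
mr.
mrs.
ms.
approx.
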