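# Example patient-list configuration.
#
# The three generator keys are the only secrets of the pseudonym
# generator; change them before any real deployment and never reuse a
# triple across instances.

idgen.k1=305419896
idgen.k2=267373481
idgen.k3=65535
idgen.id_types=pid

api.keys=sesame

linkage.first_name.error_rate=0.01
linkage.first_name.frequency=0.00005
linkage.last_name.error_rate=0.01
linkage.last_name.frequency=0.0001
linkage.birth_day.error_rate=0.01
linkage.birth_day.frequency=0.032258
linkage.birth_month.error_rate=0.01
linkage.birth_month.frequency=0.083333
linkage.birth_year.error_rate=0.01
linkage.birth_year.frequency=0.011111
linkage.threshold_match=0.95
linkage.threshold_nonmatch=0.60
linkage.exchange_groups=first_name,last_name

matching.on_tentative=create
callback.secret=
server.port=8080
storage.file=patients.sqlite
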