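category,group,term
e-cigarette,subject matter,ecig
e-cigarette,subject matter,vape
e-cigarette,subject matter,vaping
e-cigarette,subject matter,atty
e-cigarette,subject matter,carto
e-cigarette,subject matter,atomizer
e-cigarette,subject matter,cartomizer
hookah,subject matter,hookah
hookah,subject matter,waterpipe
hookah,subject matter,shisha
hookah,subject matter,mouthpiece
symptoms,health,throat
symptoms,health,cough
symptoms,health,migraine
symptoms,health,craving
quitting,health,stigma
quitting,health,stink
quitting,health,stress
quitting,health,depression
quitting,health,anxiety
quitting,health,cold turkey
perceptions,health,toxic
perceptions,health,dangerous
perceptions,health,safe
practitioners,health,doctor
practitioners,health,physician
practitioners,health,therapist
practitioners,health,counselor
social relationships,context,family
social relationships,context,friends
social relationships,context,children
setting,context,home
setting,context,bar
setting,context,party
time,context,morning
time,context,afternoon
time,context,evening
cost,context,cheap
cost,context,expensive
cost,context,price
cost,context,saving
sensory experience,context,hit
sensory experience,context,cloud
sensory experience,context,buzz
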