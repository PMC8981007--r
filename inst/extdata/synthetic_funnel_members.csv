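"member_id","months_enrolled","type2","cgm_user"
"F001",3,1,0
"F002",3,1,0
"F003",3,1,0
"F004",4,0,1
"F005",4,0,0
"F006",4,1,1
"F007",4,1,1
"F008",4,1,0
"F009",4,1,0
"F010",4,1,0
"F011",4,1,0
"F012",4,1,0
"F013",4,1,0
"F014",4,1,0
"F015",4,1,0
"F016",4,1,0
"F017",4,1,0
"F018",4,1,0
"F019",4,1,0
"F020",4,1,0
"F021",4,1,0
"F022",4,1,0
"F023",4,1,0
"F024",4,1,0
"F025",4,1,0
"F026",4,1,0
"F027",4,1,0
"F028",4,1,0
"F029",4,1,0
"F030",4,1,0
"F031",4,1,0
"F032",4,1,0
"F033",4,1,0
"F034",4,1,0
"F035",4,1,0
"F036",4,1,0
"F037",4,1,0
"F038",4,1,0
"F039",4,1,0
"F040",4,1,0
"F041",4,1,0
"F042",4,1,0
"F043",4,1,0
"F044",4,1,0
"F045",4,1,0
"F046",4,1,0
"F047",4,1,0
"F048",4,1,0
"F049",4,1,0
"F050",4,1,0
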