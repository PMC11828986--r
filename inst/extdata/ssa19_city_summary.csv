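city,total_pop_mio,pct_informal,n_facilities,n_hospitals,size_class_published
"Accra, Ghana",3.17,90.7,92,12,large
"Addis Ababa, Ethiopia",2.82,14.7,460,37,large
"Arusha, Tanzania",0.52,43.6,135,34,medium
"Bamako, Mali",3.85,84.7,215,28,large
"Beira, Mozambique",0.40,94.9,30,1,medium
"Gombe, Nigeria",0.24,96.9,218,12,small
"Ibadan, Nigeria",2.19,97.2,332,16,large
"Johannesburg, South Africa",8.22,10.0,360,21,very_large
"Kampala, Uganda",2.88,72.1,205,33,large
"Khartoum, Sudan",3.41,98.6,40,40,large
"Kigali, Rwanda",0.84,80.0,94,10,medium
"Kinshasa, Democratic Republic Congo",5.19,97.3,1337,7,very_large
"Lagos, Nigeria",8.24,95.4,265,21,very_large
"Luanda, Angola",10.94,77.8,10,9,very_large
"Lubumbashi, Democratic Republic Congo",2.27,94.3,1003,1,large
"Nakuru, Kenya",0.15,65.6,72,4,small
"Ndola, Zambia",0.33,70.7,79,0,medium
"Oyo, Nigeria",0.28,93.4,153,10,medium
"Port Elizabeth, South Africa",0.99,33.9,71,4,medium
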